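## Atlas handling: the Desikan-Killiany cortical parcellation (68 regions,
## 34 per hemisphere) and the 46-region subset shared by the EEG montage and
## the fNIRS optode coverage. ROI ordering in the shared table is fixed and
## used for every connectivity matrix and metric table in the package.

.dk_regions_34 <- c(
  "Bankssts", "Caudal anterior cingulate", "Caudal middle frontal", "Cuneus",
  "Entorhinal", "Frontal pole", "Fusiform", "Inferior parietal",
  "Inferior temporal", "Insula", "Isthmus cingulate", "Lateral occipital",
  "Lateral orbitofrontal", "Lingual", "Medial orbitofrontal",
  "Middle temporal", "Paracentral", "Parahippocampal", "Pars opercularis",
  "Pars orbitalis", "Pars triangularis", "Pericalcarine", "Postcentral",
  "Posterior cingulate", "Precentral", "Precuneus",
  "Rostral anterior cingulate", "Rostral middle frontal", "Superior frontal",
  "Superior parietal", "Superior temporal", "Supramarginal", "Temporal pole",
  "Transverse temporal"
)

#' Full Desikan-Killiany label set
#'
#' Returns the 68 cortical region labels of the Desikan-Killiany atlas in
#' the package's canonical form: `"<Region> L"` / `"<Region> R"`, regions
#' alphabetical, left before right within each region.
#'
#' @return Character vector of length 68.
#' @export
dk_labels <- function() {
  as.vector(t(outer(.dk_regions_34, c("L", "R"), paste)))
}

#' Shared EEG-fNIRS ROI table
#'
#' The 46 Desikan-Killiany regions retained because they fall inside the
#' fNIRS optode sampling area (and are therefore available to both
#' modalities), with their running number, abbreviation and lobe
#' assignment. All connectivity matrices and nodal statistics in the
#' package are ordered by the `number` column of this table.
#'
#' @return A data.frame with columns `number`, `region`, `abbreviation`,
#'   `lobe`, `lobe_abbr` (46 rows).
#' @export
roi_table <- function() {
  path <- system.file("extdata", "roi46_shared.tsv", package = "scsnet")
  abort_if(!nzchar(path), "packaged ROI table not found")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

normalize_label <- function(x) {
  x <- tolower(trimws(x))
  gsub("[^a-z]+", "", x)
}

#' Restrict an atlas to the regions covered by the optode montage
#'
#' Filters a full label set (typically the 68 Desikan-Killiany labels) down
#' to a coverage list, producing an atlas mask whose labels are ordered and
#' numbered as in [roi_table()] when the coverage equals the shared 46-ROI
#' set, and in the full set's order otherwise.
#'
#' @param full_labels Character vector of atlas labels (e.g. [dk_labels()]).
#' @param coverage Character vector of labels to retain; must be a subset of
#'   `full_labels` (matching is case/punctuation-insensitive). Defaults to
#'   the shared 46-ROI list.
#' @return An object of class `atlas_mask`: list with `labels` (retained,
#'   ordered), `index_in_full` (positions in `full_labels`) and `table`
#'   (the matching rows of [roi_table()] when applicable, else NULL).
#' @export
apply_atlas_filter <- function(full_labels = dk_labels(),
                               coverage = roi_table()$region) {
  abort_if(length(coverage) == 0, "coverage list is empty")
  full_norm <- normalize_label(full_labels)
  cov_norm <- normalize_label(coverage)
  hit <- match(cov_norm, full_norm)
  if (anyNA(hit)) {
    missing <- coverage[is.na(hit)][1]
    d <- utils::adist(normalize_label(missing), full_norm)
    stop(sprintf("unknown atlas label '%s'; did you mean '%s'?",
                 missing, full_labels[which.min(d)]), call. = FALSE)
  }
  abort_if(anyDuplicated(hit) > 0, "coverage contains duplicate labels")
  tab <- roi_table()
  tab_match <- match(cov_norm, normalize_label(tab$region))
  structure(list(
    labels = full_labels[hit],
    index_in_full = hit,
    table = if (!anyNA(tab_match)) tab[tab_match, ] else NULL
  ), class = "atlas_mask")
}

#' @export
print.atlas_mask <- function(x, ...) {
  cat(sprintf("<atlas_mask> %d regions retained\n", length(x$labels)))
  invisible(x)
}

#' Assign toy sources to ROIs
#'
#' Completes an atlas mask with a source-to-ROI assignment for a toy
#' leadfield: sources are dealt to ROIs round-robin in ROI order so that
#' every ROI has at least one source when `n_sources >= n_rois`.
#'
#' @param mask An `atlas_mask`.
#' @param n_sources Number of sources in the leadfield.
#' @return The mask with an added integer vector `source_roi` (length
#'   `n_sources`, values in `1..length(mask$labels)`).
#' @export
assign_sources <- function(mask, n_sources) {
  n_roi <- length(mask$labels)
  abort_if(n_sources < n_roi,
           "need at least one source per ROI (%d sources < %d ROIs)",
           n_sources, n_roi)
  mask$source_roi <- rep_len(seq_len(n_roi), n_sources)
  mask
}
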