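# Histology scoring: IHC H-score, positive-cell counting score, and the
# whole-slide immune-phenotype grid classification with Inflamed Score.

#' H-score per region and per case
#'
#' H-score = 3 x %(3+) + 2 x %(2+) + 1 x %(1+) over all cells of a region
#' (range 0-300); the case-level score is the unweighted mean over regions
#' (optionally weighted by cell count).
#'
#' @param cells An \code{\link{ihc_cell_table}}.
#' @param region_kind Restrict to regions of this kind (default
#'   "epithelial"); NULL for all.
#' @param weight_by_cells Weight the case mean by region cell counts.
#' @return List with \code{regions} (data.frame region_id, n_cells,
#'   h_score) and \code{case_score}.
#' @export
h_score <- function(cells, region_kind = "epithelial", weight_by_cells = FALSE) {
  stopifnot(inherits(cells, "ihc_cell_table"))
  if (!is.null(region_kind))
    cells <- cells[cells$region_kind == region_kind, , drop = FALSE]
  if (!nrow(cells)) abort_tme("no cells in the requested regions")
  regions <- do.call(rbind, lapply(split(cells, cells$region_id), function(rc) {
    n <- nrow(rc)
    pct <- vapply(1:3, function(k) 100 * sum(rc$intensity == k) / n, numeric(1))
    data.frame(region_id = rc$region_id[1], n_cells = n,
               h_score = sum(pct * 1:3), stringsAsFactors = FALSE)
  }))
  rownames(regions) <- NULL
  case <- if (weight_by_cells)
    sum(regions$h_score * regions$n_cells) / sum(regions$n_cells)
  else mean(regions$h_score)
  list(regions = regions, case_score = case)
}

#' Positive-cell counting score per region and per case
#'
#' Cells with staining intensity >= 1+ are positive; the score is positive
#' cells per mm^2 of region area, averaged (unweighted) over regions for the
#' case score.
#'
#' @param cells An \code{\link{ihc_cell_table}}.
#' @param region_kind Restrict to regions of this kind (default "TIL");
#'   NULL for all.
#' @return List with \code{regions} (region_id, n_cells, n_positive,
#'   area_mm2, counting_score) and \code{case_score}.
#' @export
counting_score <- function(cells, region_kind = "TIL") {
  stopifnot(inherits(cells, "ihc_cell_table"))
  if (!is.null(region_kind))
    cells <- cells[cells$region_kind == region_kind, , drop = FALSE]
  if (!nrow(cells)) abort_tme("no cells in the requested regions")
  regions <- do.call(rbind, lapply(split(cells, cells$region_id), function(rc) {
    area <- rc$region_area_mm2[1]
    npos <- sum(rc$intensity >= 1)
    data.frame(region_id = rc$region_id[1], n_cells = nrow(rc),
               n_positive = npos, area_mm2 = area,
               counting_score = npos / area, stringsAsFactors = FALSE)
  }))
  rownames(regions) <- NULL
  list(regions = regions, case_score = mean(regions$counting_score))
}

#' Immune-phenotype class of a grid
#'
#' Inflamed when intratumoral TIL density >= 130/mm^2; otherwise
#' immune-excluded when stromal density >= 260/mm^2; immune-desert when
#' below both thresholds.
#'
#' @param intratumoral_density,stromal_density Densities in cells/mm^2
#'   (vectors allowed, recycled pairwise).
#' @param inflamed_thresh,excluded_thresh The two density thresholds.
#' @return Character vector in {"inflamed", "excluded", "desert"}.
#' @export
classify_ip <- function(intratumoral_density, stromal_density,
                        inflamed_thresh = 130, excluded_thresh = 260) {
  if (any(intratumoral_density < 0) || any(stromal_density < 0) ||
      any(!is.finite(intratumoral_density)) || any(!is.finite(stromal_density)))
    abort_tme("TIL densities must be finite and nonnegative")
  ifelse(intratumoral_density >= inflamed_thresh, "inflamed",
  ifelse(stromal_density >= excluded_thresh, "excluded", "desert"))
}

#' Whole-slide Inflamed Score
#'
#' Classifies every grid of a slide and returns the proportion of grids per
#' immune-phenotype class; the Inflamed Score is the inflamed-class
#' proportion.
#'
#' @param grid A \code{\link{til_grid}}.
#' @param ... Threshold overrides passed to \code{\link{classify_ip}}.
#' @return List: \code{classes} (per-grid data.frame), \code{proportions}
#'   (named: inflamed, excluded, desert; sums to 1), \code{inflamed_score}.
#' @export
inflamed_score <- function(grid, ...) {
  stopifnot(inherits(grid, "til_grid"))
  if (!nrow(grid)) abort_tme("empty grid set")
  cls <- classify_ip(grid$intratumoral_density, grid$stromal_density, ...)
  props <- vapply(c("inflamed", "excluded", "desert"),
                  function(k) mean(cls == k), numeric(1))
  list(classes = data.frame(grid_id = grid$grid_id, ip_class = cls,
                            stringsAsFactors = FALSE),
       proportions = props, inflamed_score = unname(props["inflamed"]))
}
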