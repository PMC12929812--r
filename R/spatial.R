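# Visium-style spatial analysis: hexagonal first-ring neighbors in array
# coordinates, 7-spot pseudo-spot aggregation with the >= 4-member retention
# rule, slide-level expressing-fraction filtering, median-quadrant
# co-expression classes, and spot/pseudo-spot correlation.

HEX_OFFSETS <- cbind(dr = c(0L, 0L, 1L, 1L, -1L, -1L),
                     dc = c(2L, -2L, 1L, -1L, 1L, -1L))

#' First-ring hexagonal neighbors of a spot
#'
#' In Visium array coordinates (row + col even) the six first-ring
#' neighbors of a spot sit at offsets (0, +/-2) and (+/-1, +/-1). Only
#' neighbors present in the grid are returned.
#'
#' @param barcode Barcode of a spot in \code{grid}.
#' @param grid A \code{\link{spot_grid}}.
#' @return Character vector of up to 6 neighbor barcodes.
#' @export
hex_neighbors <- function(barcode, grid) {
  stopifnot(inherits(grid, "spot_grid"))
  i <- match(barcode, grid$barcode)
  if (is.na(i)) abort_tme("spot '%s' not in grid", barcode)
  key <- paste(grid$array_row, grid$array_col)
  nb_key <- paste(grid$array_row[i] + HEX_OFFSETS[, "dr"],
                  grid$array_col[i] + HEX_OFFSETS[, "dc"])
  grid$barcode[match(nb_key, key, nomatch = 0L)]
}

#' Build pseudo-spots by first-ring aggregation
#'
#' One candidate pseudo-spot per spot: the center plus its existing
#' first-ring neighbors (1-7 members; windows overlap). Gene counts are
#' summed exactly over members. Pseudo-spots with fewer than
#' \code{min_members} members are flagged as not retained.
#'
#' @param grid A \code{\link{spot_grid}}.
#' @param min_members Retention threshold on member count (default 4).
#' @return data.frame of class \code{pseudospot_table}: center_barcode,
#'   n_members, retained, plus one summed-count column per gene;
#'   \code{attr(, "members")} is a list of member barcodes per center.
#' @export
build_pseudospots <- function(grid, min_members = 4) {
  stopifnot(inherits(grid, "spot_grid"))
  check_count(min_members, "min_members", lower = 1)
  genes <- attr(grid, "genes")
  key <- paste(grid$array_row, grid$array_col)
  n <- nrow(grid)
  members <- vector("list", n)
  gm <- as.matrix(as.data.frame(grid)[, genes, drop = FALSE])
  sums <- matrix(0, n, length(genes), dimnames = list(NULL, genes))
  n_members <- integer(n)
  for (i in seq_len(n)) {
    nb_key <- paste(grid$array_row[i] + HEX_OFFSETS[, "dr"],
                    grid$array_col[i] + HEX_OFFSETS[, "dc"])
    idx <- c(i, match(nb_key, key, nomatch = 0L))
    idx <- idx[idx > 0L]
    members[[i]] <- grid$barcode[idx]
    n_members[i] <- length(idx)
    sums[i, ] <- colSums(gm[idx, , drop = FALSE])
  }
  out <- data.frame(center_barcode = grid$barcode, n_members = n_members,
                    retained = n_members >= min_members,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(sums))
  rownames(out) <- NULL
  structure(out, class = c("pseudospot_table", "data.frame"),
            members = setNames(members, grid$barcode), genes = genes,
            min_members = min_members)
}

#' Median-quadrant co-expression classes
#'
#' Each unit (spot or retained pseudo-spot) is classified into high-high /
#' high-low / low-high / low-low for an (anchor, target) gene pair, "high"
#' meaning strictly above that gene's median over the units being
#' classified.
#'
#' @param anchor_values,target_values Aligned numeric vectors.
#' @return Character vector of quadrant labels
#'   (\code{"<anchor>-<target>"} in {high,low} x {high,low}).
#' @export
quadrant_classify <- function(anchor_values, target_values) {
  if (length(anchor_values) != length(target_values))
    abort_tme("anchor and target value vectors differ in length")
  a <- ifelse(anchor_values > median(anchor_values), "high", "low")
  t <- ifelse(target_values > median(target_values), "high", "low")
  paste(a, t, sep = "-")
}

#' Slide filter on expressing-spot fraction
#'
#' A slide passes when the fraction of spots with a nonzero count for
#' \code{gene} strictly exceeds \code{min_frac} (default 5%).
#'
#' @param grid A \code{\link{spot_grid}}.
#' @param gene Gene column name.
#' @param min_frac Fraction threshold (default 0.05).
#' @return TRUE/FALSE, with the fraction as \code{attr(, "frac")}.
#' @export
slide_filter <- function(grid, gene, min_frac = 0.05) {
  stopifnot(inherits(grid, "spot_grid"))
  if (!gene %in% attr(grid, "genes")) abort_tme("gene '%s' absent from grid", gene)
  frac <- mean(grid[[gene]] > 0)
  structure(frac > min_frac, frac = frac)
}

#' Correlation between two genes over spatial units
#'
#' Pearson correlation across spots or retained pseudo-spots, by default on
#' log2(1 + count) values (\code{transform = "log2"}); \code{"raw"} uses
#' the counts/sums directly.
#'
#' @param anchor_values,target_values Aligned numeric vectors (>= 3 units).
#' @param transform \code{"log2"} (default) or \code{"raw"}.
#' @return Pearson r (NA with a warning on zero variance).
#' @export
spot_correlation <- function(anchor_values, target_values,
                             transform = c("log2", "raw")) {
  transform <- match.arg(transform)
  if (transform == "log2") {
    anchor_values <- log2(1 + anchor_values)
    target_values <- log2(1 + target_values)
  }
  pearson_r(anchor_values, target_values)
}

#' Per-slide co-expression analysis
#'
#' Convenience wrapper: applies the expressing-fraction filter, computes
#' spot-level and pseudo-spot-level correlation between an anchor and a
#' target gene, and the quadrant class counts at both resolutions.
#'
#' @param grid A \code{\link{spot_grid}} containing both genes.
#' @param anchor,target Gene column names.
#' @param min_frac Expressing-fraction threshold on the target gene.
#' @param min_members Pseudo-spot retention threshold.
#' @param transform Passed to \code{\link{spot_correlation}}.
#' @return List: pass_filter, expressing_frac, n_spots,
#'   n_pseudospots_retained, r_spot, r_pseudospot, quadrants_spot,
#'   quadrants_pseudospot.
#' @export
analyze_slide <- function(grid, anchor, target, min_frac = 0.05,
                          min_members = 4, transform = "log2") {
  pass <- slide_filter(grid, target, min_frac = min_frac)
  ps <- build_pseudospots(grid, min_members = min_members)
  kept <- ps[ps$retained, , drop = FALSE]
  r_spot <- spot_correlation(grid[[anchor]], grid[[target]], transform)
  r_ps <- if (nrow(kept) >= 3)
    spot_correlation(kept[[anchor]], kept[[target]], transform) else NA_real_
  qs <- table(quadrant_classify(grid[[anchor]], grid[[target]]))
  qp <- if (nrow(kept))
    table(quadrant_classify(kept[[anchor]], kept[[target]])) else table(character())
  list(pass_filter = as.logical(pass), expressing_frac = attr(pass, "frac"),
       n_spots = nrow(grid), n_pseudospots_retained = nrow(kept),
       r_spot = r_spot, r_pseudospot = r_ps,
       quadrants_spot = qs, quadrants_pseudospot = qp)
}
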