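# Registration quality metrics: DICE, mean distance to agreement, Jacobian
# statistics, and one-tailed Wilcoxon-Mann-Whitney cohort comparisons.

as_mask_array <- function(x) {
  if (inherits(x, "label_map")) return(x$labels > 0L)
  if (is.array(x) && is.logical(x)) return(x)
  stop("expected a label_map or logical array", call. = FALSE)
}

#' DICE similarity coefficient of two masks
#'
#' `2 |A intersect B| / (|A| + |B|)` over voxelized masks on a shared grid.
#' The conventional threshold for acceptable boundary agreement in DIR QA
#' is DSC >= 0.8.
#'
#' @param a,b [label_map()] objects (any nonzero voxel counts) or logical
#'   arrays of identical shape.
#' @return DSC in `[0, 1]`; both masks empty is an error.
#' @export
dice <- function(a, b) {
  if (inherits(a, "label_map") && inherits(b, "label_map") &&
      !same_grid(a$grid, b$grid))
    stop("dice: masks live on different grids", call. = FALSE)
  A <- as_mask_array(a); B <- as_mask_array(b)
  if (!identical(dim(A), dim(B)))
    stop("dice: masks have different shapes", call. = FALSE)
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0L)
    stop("dice: both masks are empty", call. = FALSE)
  2 * sum(A & B) / (na + nb)
}

# chunked nearest-neighbour distances from each row of A to the set B
nearest_dists <- function(A, B, chunk = 512L) {
  A <- as.matrix(A); B <- as.matrix(B)
  b2 <- rowSums(B^2)
  out <- numeric(nrow(A))
  for (i0 in seq(1L, nrow(A), by = chunk)) {
    ii <- i0:min(nrow(A), i0 + chunk - 1L)
    d2 <- outer(rowSums(A[ii, , drop = FALSE]^2), b2, "+") -
      2 * A[ii, , drop = FALSE] %*% t(B)
    out[ii] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Mean distance to agreement between two surfaces
#'
#' Symmetric mean surface distance: the average of the two directed mean
#' nearest-point distances. The conventional DIR QA threshold is 3 mm.
#'
#' @param surface_a,surface_b point sets (n x 3 matrices, mm), both
#'   nonempty.
#' @param directed `"symmetric"` (default), `"a_to_b"` or `"b_to_a"`.
#' @return Mean distance in mm.
#' @export
mda <- function(surface_a, surface_b,
                directed = c("symmetric", "a_to_b", "b_to_a")) {
  directed <- match.arg(directed)
  surface_a <- as.matrix(surface_a); surface_b <- as.matrix(surface_b)
  if (nrow(surface_a) == 0L || nrow(surface_b) == 0L)
    stop("mda: empty surface", call. = FALSE)
  switch(directed,
         a_to_b = mean(nearest_dists(surface_a, surface_b)),
         b_to_a = mean(nearest_dists(surface_b, surface_a)),
         symmetric = (mean(nearest_dists(surface_a, surface_b)) +
                      mean(nearest_dists(surface_b, surface_a))) / 2)
}

#' Jacobian-determinant statistics over a region
#'
#' Population mean and standard deviation of the Jacobian determinant over
#' the region's voxels, plus the fraction falling in the physiological
#' range `[0.8, 1.2]`. STD-JD is the interior-uncertainty measure: a
#' registration that deforms an organ's interior erratically has a large
#' STD-JD even when its surfaces match well.
#'
#' @param jmap a `jacobian_map` from [jacobian_determinant_map()].
#' @param roi a [label_map()] or logical array selecting the region
#'   (nonempty).
#' @param exclude_shell drop a 1-voxel shell at the grid faces, where the
#'   Jacobian uses one-sided differences (default off).
#' @return `list(mean_jd, std_jd, frac_in_range)`.
#' @export
jd_stats <- function(jmap, roi, exclude_shell = FALSE) {
  stopifnot(inherits(jmap, "jacobian_map"))
  sel <- as_mask_array(roi)
  if (!identical(dim(sel), dim(jmap$values)))
    stop("jd_stats: roi shape does not match the Jacobian map", call. = FALSE)
  if (exclude_shell) {
    n <- dim(sel)
    shell <- array(TRUE, n)
    shell[2:(n[1] - 1), 2:(n[2] - 1), 2:(n[3] - 1)] <- FALSE
    sel <- sel & !shell
  }
  v <- jmap$values[sel]
  if (!length(v)) stop("jd_stats: empty roi", call. = FALSE)
  m <- mean(v)
  list(mean_jd = m,
       std_jd = sqrt(mean((v - m)^2)),
       frac_in_range = mean(v >= 0.8 & v <= 1.2))
}

#' One-tailed Wilcoxon-Mann-Whitney test
#'
#' Rank-sum test on the Mann-Whitney U statistic with midranks for ties.
#' For pooled samples of at most 12 tie-free observations the p-value is
#' exact, by enumeration of all assignments; otherwise the normal
#' approximation with tie-corrected variance and continuity correction is
#' used. `alternative = "less"` tests whether `x` tends to be smaller than
#' `y`. A degenerate pooled sample (all values equal) returns p = 0.5 with
#' a warning.
#'
#' @param x,y numeric samples, each of size >= 3.
#' @param alternative `"less"` or `"greater"`.
#' @return The one-tailed p-value.
#' @examples
#' wmw_one_tailed(c(1, 2, 3), c(4, 5, 6), "less")  # exact 1/20 = 0.05
#' @export
wmw_one_tailed <- function(x, y, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) < 3L || length(y) < 3L)
    stop("wmw_one_tailed: both samples must have >= 3 observations",
         call. = FALSE)
  pooled <- c(x, y)
  if (any(!is.finite(pooled)))
    stop("wmw_one_tailed: non-finite values", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (max(pooled) == min(pooled)) {
    warning("wmw_one_tailed: degenerate all-equal pooled sample; p = 0.5")
    return(0.5)
  }
  r <- rank(pooled)            # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  if (N <= 12L && !ties) {
    # exact: enumerate every choice of n1 ranks out of N
    combos <- utils::combn(N, n1)
    Us <- colSums(matrix(seq_len(N)[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- if (alternative == "less") mean(Us <= U) else mean(Us >= U)
    return(p)
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    warning("wmw_one_tailed: zero variance after tie correction; p = 0.5")
    return(0.5)
  }
  if (alternative == "less")
    stats::pnorm((U - mu + 0.5) / sqrt(sigma2))
  else
    stats::pnorm(-(U - mu - 0.5) / sqrt(sigma2))
}

#' Paired one-tailed Wilcoxon signed-rank test
#'
#' Companion to [wmw_one_tailed()] for paired per-organ designs; a thin
#' interface over [stats::wilcox.test()] with `paired = TRUE`.
#'
#' @inheritParams wmw_one_tailed
#' @return The one-tailed p-value.
#' @export
signed_rank_one_tailed <- function(x, y, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, alternative = alternative,
                       exact = FALSE, correct = TRUE)$p.value)
}

#' Evaluate a registration against reference structures
#'
#' Warps each moving structure mask by the field (nearest-neighbour
#' pull-back), then computes DSC against the reference mask, MDA between
#' the warped and reference surfaces, and Jacobian statistics over the
#' reference structure (or supplied ROI). Structures are flagged when
#' MDA > 3 mm or DSC < 0.8, the usual boundary-accuracy thresholds.
#'
#' @param field a [displacement_field()].
#' @param ref_structures,mov_structures lists of [structure_surface()]
#'   objects paired by name.
#' @param rois optional named list of [label_map()] ROIs for the Jacobian
#'   statistics; defaults to each reference structure's mask.
#' @return A `metric_report` data.frame: one row per structure with
#'   `dsc`, `mda`, `mean_jd`, `std_jd`, `frac_jd_in_range`, `flagged`.
#' @export
evaluate_registration <- function(field, ref_structures, mov_structures,
                                  rois = NULL) {
  if (inherits(ref_structures, "structure_surface"))
    ref_structures <- list(ref_structures)
  if (inherits(mov_structures, "structure_surface"))
    mov_structures <- list(mov_structures)
  mov_names <- vapply(mov_structures, `[[`, character(1), "name")
  jmap <- jacobian_determinant_map(field)
  rows <- lapply(ref_structures, function(rs) {
    j <- match(rs$name, mov_names)
    if (is.na(j))
      stop("evaluate_registration: no moving structure named '", rs$name,
           "'", call. = FALSE)
    warped <- warp_mask_backward(mov_structures[[j]]$mask, field)
    d <- dice(rs$mask, warped)
    wm <- if (any(warped$labels > 0L))
      mda(rs$points, mask_to_surface_points(warped)) else Inf
    roi <- if (!is.null(rois) && !is.null(rois[[rs$name]])) rois[[rs$name]]
           else rs$mask
    js <- jd_stats(jmap, roi)
    data.frame(structure = rs$name, dsc = d, mda = wm,
               mean_jd = js$mean_jd, std_jd = js$std_jd,
               frac_jd_in_range = js$frac_in_range,
               flagged = (wm > 3) | (d < 0.8))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("metric_report", "data.frame")
  out
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  cat("Registration metric report\n")
  df <- as.data.frame(x)
  df$dsc <- round(df$dsc, digits)
  df$mda <- round(df$mda, digits)
  df$mean_jd <- round(df$mean_jd, digits)
  df$std_jd <- round(df$std_jd, digits)
  df$frac_jd_in_range <- round(df$frac_jd_in_range, digits)
  print(df, row.names = FALSE)
  if (any(x$flagged))
    cat("flagged: MDA > 3 mm or DSC < 0.8 for ",
        paste(x$structure[x$flagged], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a metric report to CSV or JSON
#'
#' @param report a `metric_report` (or any data.frame).
#' @param path output path ending in `.csv` or `.json`.
#' @return The path, invisibly.
#' @export
write_metric_report <- function(report, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE))
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(as.data.frame(report), path, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  else stop("write_metric_report: path must end in .csv or .json",
            call. = FALSE)
  invisible(path)
}
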