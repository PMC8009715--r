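#' Gray-level run-length matrix
#'
#' Counts maximal runs of equal gray value along one of the four standard
#' directions.  Entry `counts[i, j]` is the number of maximal runs of
#' gray level `i - 1` (levels 0-based) and length `j`.
#'
#' @param image a [gray_image]; quantize first for practical matrices.
#' @param direction one of `0`, `45`, `90`, `135` (degrees).  0 runs along
#'   rows, 90 along columns, 45 along up-right anti-diagonals, 135 along
#'   down-right diagonals.
#' @return object of class `glrlm`: list with `counts`
#'   (`n_levels` x `max_run`), `direction`, `n_runs`, `n_pixels`.
#'   Every pixel belongs to exactly one run, so
#'   `sum(j * counts[, j]) == n_pixels`.
#' @seealso [glrlm_features()]
#' @export
glrlm <- function(image, direction = 0) {
  image <- as_gray_image(image)
  if (!direction %in% c(0, 45, 90, 135))
    stop("'direction' must be one of 0, 45, 90, 135")
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  lines <- switch(as.character(direction),
    "0"   = split(as.vector(t(px)), rep(seq_len(nr), each = nc)),
    "90"  = split(as.vector(px), rep(seq_len(nc), each = nr)),
    # anti-diagonals (up-right): constant row + col
    "45"  = split(as.vector(px),
                  as.vector(row(px) + col(px))),
    # diagonals (down-right): constant row - col
    "135" = split(as.vector(px),
                  as.vector(row(px) - col(px))))
  g <- image$n_levels
  max_run <- max(nr, nc)
  counts <- matrix(0L, g, max_run)
  for (ln in lines) {
    r <- rle(ln)
    idx <- cbind(r$values + 1L, r$lengths)
    for (k in seq_along(r$values))
      counts[idx[k, 1L], idx[k, 2L]] <- counts[idx[k, 1L], idx[k, 2L]] + 1L
  }
  used <- max(which(colSums(counts) > 0L))
  counts <- counts[, seq_len(used), drop = FALSE]
  structure(list(counts = counts, direction = direction,
                 n_runs = sum(counts), n_pixels = nr * nc),
            class = "glrlm")
}

#' @export
print.glrlm <- function(x, ...) {
  cat(sprintf("<glrlm %dx%d, %d deg, %d runs over %d pixels>\n",
              nrow(x$counts), ncol(x$counts), x$direction, x$n_runs,
              x$n_pixels))
  invisible(x)
}

glrlm_feature_names <- c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre")

#' Run-length texture statistics
#'
#' The seven classical Galloway/Chu run-length features, with `P(i, j)`
#' the run counts, `n` the total number of runs, gray index `i` counted
#' from 1 and run length `j` from 1:
#' short-run emphasis `SRE = (1/n) sum P(i,j)/j^2`, long-run emphasis
#' `LRE = (1/n) sum j^2 P(i,j)`, gray-level nonuniformity
#' `GLN = (1/n) sum_i (sum_j P(i,j))^2`, run-length nonuniformity
#' `RLN = (1/n) sum_j (sum_i P(i,j))^2`, run percentage
#' `RP = n / n_pixels`, low gray-level run emphasis
#' `LGRE = (1/n) sum P(i,j)/i^2`, and high gray-level run emphasis
#' `HGRE = (1/n) sum i^2 P(i,j)`.
#'
#' @param rlm a [glrlm].
#' @return named numeric vector of length 7.
#' @export
glrlm_features <- function(rlm) {
  if (!inherits(rlm, "glrlm")) stop("'rlm' must be a glrlm object")
  p <- rlm$counts
  n <- rlm$n_runs
  if (n == 0L) stop("empty run-length matrix")
  i <- seq_len(nrow(p))
  j <- seq_len(ncol(p))
  ri <- rowSums(p)
  rj <- colSums(p)
  out <- c(
    sre  = sum(t(p) / j^2) / n,
    lre  = sum(t(p) * j^2) / n,
    gln  = sum(ri^2) / n,
    rln  = sum(rj^2) / n,
    rp   = n / rlm$n_pixels,
    lgre = sum(p / i^2) / n,
    hgre = sum(p * i^2) / n)
  names(out) <- glrlm_feature_names
  out
}
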