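#' Bound/unbound state partition on one collective variable
#'
#' Splits configuration space by a threshold on a single CV, e.g. the
#' published definition of bound and unbound oligomer pairs as centre-of-
#' mass distances below and above 3 nm. Frames exactly at the threshold
#' count as bound.
#'
#' @param cv_name CV to partition on (e.g. "d_COM", "d1", "s").
#' @param threshold nm.
#' @param bound which side is the bound state: "below" or "above".
#' @return An object of class `state_partition`.
#' @export
state_partition <- function(cv_name, threshold = 3, bound = c("below", "above")) {
  bound <- match.arg(bound)
  stopifnot(is.finite(threshold))
  structure(list(cv_name = cv_name, threshold = threshold, bound = bound),
            class = "state_partition")
}

is_bound <- function(partition, x) {
  if (partition$bound == "below") x <= partition$threshold
  else x >= partition$threshold
}

#' Free-energy difference result
#'
#' @param dF free-energy difference, kJ/mol.
#' @param error standard error, kJ/mol (>= 0).
#' @param window descriptor of the data window used.
#' @param system system label.
#' @param temperature K.
#' @param partition the [state_partition()] used, if any.
#' @return An object of class `free_energy_result`.
#' @export
free_energy_result <- function(dF, error = 0, window = "full", system = "unknown",
                               temperature = 300, partition = NULL) {
  stopifnot(is.finite(dF), error >= 0)
  structure(list(dF = dF, error = error, window = window, system = system,
                 temperature = temperature, partition = partition),
            class = "free_energy_result")
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat(sprintf("dF = %.3f +/- %.3f kJ/mol  [%s, %s, T = %g K]\n",
              x$dF, x$error, x$system, x$window, x$temperature))
  invisible(x)
}

#' Metadynamics reweighting: per-frame statistical weights
#'
#' Final-bias (umbrella-like) reweighting: each frame i gets weight
#' `w_i proportional to exp(+V_final(s_i) / kB T)`, where `V_final` is the
#' fully deposited bias evaluated at the frame's biased-CV values. Weights
#' are normalized to sum 1. An optional transient fraction of initial
#' frames (deposited while the bias was still far from stationary) can be
#' excluded by giving it zero weight.
#'
#' @param traj a [cv_trajectory()] containing the biased CV columns.
#' @param bias the final [metad_bias()] of the run, or `NULL` for an
#'   unbiased trajectory (uniform weights).
#' @param temperature K; defaults to the trajectory's metadata.
#' @param transient fraction of initial frames excluded (default 0; the
#'   detachment workflow uses 0.2).
#' @return Numeric weight per frame, summing to 1.
#' @export
frame_weights <- function(traj, bias, temperature = attr(traj, "temperature"),
                          transient = 0) {
  stopifnot(is.data.frame(traj), nrow(traj) > 0,
            transient >= 0, transient < 1)
  n <- nrow(traj)
  if (is.null(bias)) {
    logw <- rep(0, n)
  } else {
    missing_cv <- setdiff(bias$cv_names, names(traj))
    if (length(missing_cv) > 0)
      stop("trajectory lacks biased CV column(s): ",
           paste(missing_cv, collapse = ", "))
    logw <- if (length(bias$heights) == 0) rep(0, n) else
      evaluate_bias(bias, as.matrix(traj[bias$cv_names])) / kBT(temperature)
  }
  w <- exp(logw - max(logw))
  if (transient > 0) w[seq_len(floor(n * transient))] <- 0
  s <- sum(w)
  if (s <= 0) stop("zero total weight")
  w / s
}

#' Weighted free-energy surface on one or two collective variables
#'
#' Histograms the (reweighted) trajectory and converts populations to free
#' energies, `F = -kB T log(sum of weights in bin)`, shifting the minimum
#' over occupied bins to zero. Unoccupied bins are flagged `NA`, never 0.
#'
#' @param traj a [cv_trajectory()].
#' @param weights per-frame weights from [frame_weights()] (or uniform).
#' @param cv_names one or two CV column names.
#' @param bins number of bins per CV (scalar or per-CV), or a list of
#'   explicit break vectors.
#' @param temperature K.
#' @param n_blocks if not `NULL`, fill per-bin errors by [block_error()]
#'   (1-D only).
#' @return An object of class `fes_grid`: `centers`, `edges`, `F` (vector
#'   or matrix, kJ/mol, min 0), `error`, `occupied`.
#' @export
make_fes <- function(traj, weights = NULL, cv_names, bins = 100,
                     temperature = attr(traj, "temperature"),
                     n_blocks = NULL) {
  stopifnot(is.data.frame(traj), length(cv_names) %in% 1:2,
            all(cv_names %in% names(traj)))
  n <- nrow(traj)
  if (is.null(weights)) weights <- rep(1 / n, n)
  stopifnot(length(weights) == n)
  if (sum(weights) <= 0) stop("zero total weight")
  weights <- weights / sum(weights)

  edges <- .fes_edges(traj, cv_names, bins)
  idx <- lapply(seq_along(cv_names), function(d)
    .bin_index(traj[[cv_names[d]]], edges[[d]]))
  kT <- kBT(temperature)

  if (length(cv_names) == 1L) {
    nb <- length(edges[[1]]) - 1L
    p <- vapply(seq_len(nb), function(b) sum(weights[which(idx[[1]] == b)]),
                numeric(1))
    occupied <- p > 0
    F <- ifelse(occupied, -kT * log(p), NA_real_)
    F <- F - min(F[occupied])
    err <- rep(NA_real_, nb)
    if (!is.null(n_blocks))
      err <- block_error(traj, weights, cv_names, bins = edges[[1]],
                         n_blocks = n_blocks, temperature = temperature)
  } else {
    nb1 <- length(edges[[1]]) - 1L; nb2 <- length(edges[[2]]) - 1L
    p <- matrix(0, nb1, nb2)
    ok <- idx[[1]] >= 1 & idx[[2]] >= 1
    for (f in which(ok)) p[idx[[1]][f], idx[[2]][f]] <-
        p[idx[[1]][f], idx[[2]][f]] + weights[f]
    occupied <- p > 0
    F <- ifelse(occupied, -kT * log(p), NA_real_)
    F <- F - min(F[occupied])
    err <- matrix(NA_real_, nb1, nb2)
  }
  structure(
    list(cv_names = cv_names, edges = edges,
         centers = lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2),
         F = F, error = err, occupied = occupied, temperature = temperature),
    class = "fes_grid")
}

.fes_edges <- function(traj, cv_names, bins) {
  if (is.list(bins)) return(bins)
  bins <- rep_len(bins, length(cv_names))
  lapply(seq_along(cv_names), function(d) {
    x <- traj[[cv_names[d]]]
    if (length(bins) >= d && length(bins[d]) == 1 && bins[d] > 1) {
      r <- range(x)
      if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
      seq(r[1], r[2], length.out = bins[d] + 1)
    } else stop("bins must be a positive count or a list of break vectors")
  })
}

.bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i < 1 | i > length(edges) - 1] <- NA_integer_
  i
}

#' Block-analysis error of a free-energy profile
#'
#' Splits the trajectory into `n_blocks` contiguous blocks (remainder
#' frames joining the last), computes a weighted probability profile per
#' block, and propagates the standard error of the mean probability into a
#' per-bin free-energy error: `sigma_F = kB T * SE(p) / mean(p)`. For
#' weakly correlated frames this matches bootstrap errors; block errors are
#' invariant to a constant shift of the bias because weights are
#' renormalized within each block.
#'
#' @param traj a [cv_trajectory()].
#' @param weights per-frame weights.
#' @param cv_name single CV name.
#' @param bins bin count or explicit break vector.
#' @param n_blocks number of contiguous blocks (>= 2).
#' @param temperature K.
#' @return Per-bin standard error, kJ/mol (NA for bins never occupied).
#' @export
block_error <- function(traj, weights, cv_name, bins = 100, n_blocks = 5,
                        temperature = attr(traj, "temperature")) {
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  stopifnot(length(cv_name) == 1, cv_name %in% names(traj))
  n <- nrow(traj)
  if (is.null(weights)) weights <- rep(1 / n, n)
  edges <- if (length(bins) > 1) bins else
    .fes_edges(traj, cv_name, bins)[[1]]
  nb <- length(edges) - 1L
  idx <- .bin_index(traj[[cv_name]], edges)
  block_of <- pmin(floor((seq_len(n) - 1) / max(n %/% n_blocks, 1)) + 1,
                   n_blocks)
  pmat <- matrix(0, n_blocks, nb)
  for (b in seq_len(n_blocks)) {
    w <- weights[block_of == b]
    i <- idx[block_of == b]
    if (sum(w) > 0) {
      w <- w / sum(w)
      for (bin in seq_len(nb)) pmat[b, bin] <- sum(w[i == bin], na.rm = TRUE)
    }
  }
  pbar <- colMeans(pmat)
  se_p <- apply(pmat, 2, sd) / sqrt(n_blocks)
  ifelse(pbar > 0, kBT(temperature) * se_p / pbar, NA_real_)
}

#' Bound/unbound free-energy difference by state integration
#'
#' Integrates the Boltzmann-weighted populations over the two regions of a
#' [state_partition()] and returns
#' `dF = -kB T log(P_bound / P_unbound)`; negative values mean the bound
#' state is favored. The quoted error is a block-analysis standard error
#' over contiguous blocks.
#'
#' @param traj a [cv_trajectory()] containing the partition CV.
#' @param weights per-frame weights (uniform if `NULL`).
#' @param partition a [state_partition()].
#' @param temperature K.
#' @param n_blocks blocks for the error estimate.
#' @return A [free_energy_result()].
#' @export
state_delta_f <- function(traj, weights = NULL, partition,
                          temperature = attr(traj, "temperature"),
                          n_blocks = 5) {
  stopifnot(inherits(partition, "state_partition"),
            partition$cv_name %in% names(traj))
  n <- nrow(traj)
  if (is.null(weights)) weights <- rep(1 / n, n)
  x <- traj[[partition$cv_name]]
  bnd <- is_bound(partition, x)
  wb <- sum(weights[bnd]); wu <- sum(weights[!bnd])
  if (!is.finite(wb) || !is.finite(wu) || wb <= 0 || wu <= 0)
    stop("undefined dF: a partition region holds no statistical weight")
  kT <- kBT(temperature)
  dF <- -kT * log(wb / wu)
  block_of <- pmin(floor((seq_len(n) - 1) / max(n %/% n_blocks, 1)) + 1,
                   n_blocks)
  dfb <- vapply(seq_len(n_blocks), function(b) {
    sel <- block_of == b
    a <- sum(weights[sel & bnd]); u <- sum(weights[sel & !bnd])
    if (a > 0 && u > 0) -kT * log(a / u) else NA_real_
  }, numeric(1))
  err <- if (sum(!is.na(dfb)) >= 2)
    sd(dfb, na.rm = TRUE) / sqrt(sum(!is.na(dfb))) else 0
  free_energy_result(dF, err, window = sprintf("frames 1-%d", n),
                     system = attr(traj, "system") %||% "unknown",
                     temperature = temperature, partition = partition)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convergence of the bound/unbound free-energy difference
#'
#' Recomputes [state_delta_f()] on growing trajectory prefixes, from
#' `window` frames up to the full length in steps of `stride` (the final
#' entry always uses the whole trajectory), mirroring the accumulated-
#' simulation-time convergence plots of detachment free energies.
#'
#' @param traj,weights,partition,temperature as [state_delta_f()].
#' @param window first prefix length, frames.
#' @param stride prefix increment, frames (> 0).
#' @return A data frame with columns `frames`, `dF`, `error`.
#' @export
convergence_series <- function(traj, weights = NULL, partition, window,
                               stride, temperature = attr(traj, "temperature")) {
  n <- nrow(traj)
  if (stride <= 0) stop("stride must be positive")
  if (window > n) stop("window longer than trajectory")
  if (is.null(weights)) weights <- rep(1 / n, n)
  ends <- unique(c(seq(window, n, by = stride), n))
  # prefixes holding no statistical weight (e.g. entirely inside a
  # discarded transient) are skipped
  ends <- ends[vapply(ends, function(e) sum(weights[seq_len(e)]) > 0,
                      logical(1))]
  rows <- lapply(ends, function(e) {
    pre <- traj[seq_len(e), , drop = FALSE]
    attr(pre, "temperature") <- temperature
    attr(pre, "system") <- attr(traj, "system")
    r <- state_delta_f(pre, weights[seq_len(e)] / sum(weights[seq_len(e)]),
                       partition, temperature = temperature)
    data.frame(frames = e, dF = r$dF, error = r$error)
  })
  do.call(rbind, rows)
}

#' Relative free-energy difference between two systems
#'
#' `ddF = dF_a - dF_b` with errors added in quadrature; e.g. the extra
#' detachment cost of crystalline over amorphous chains. Both results must
#' share temperature and partition semantics.
#'
#' @param result_a,result_b [free_energy_result()] objects.
#' @return A [free_energy_result()] for the difference.
#' @export
delta_delta_f <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "free_energy_result"),
            inherits(result_b, "free_energy_result"))
  if (!isTRUE(all.equal(result_a$temperature, result_b$temperature)))
    stop("mismatched temperatures")
  pa <- result_a$partition; pb <- result_b$partition
  if (!is.null(pa) && !is.null(pb) &&
      (pa$threshold != pb$threshold || pa$bound != pb$bound))
    stop("mismatched state partitions")
  free_energy_result(
    result_a$dF - result_b$dF,
    sqrt(result_a$error^2 + result_b$error^2),
    window = paste(result_a$window, "vs", result_b$window),
    system = paste(result_a$system, "-", result_b$system),
    temperature = result_a$temperature, partition = pa)
}

#' Write a free-energy profile as a COLVAR-style table
#'
#' @param fes an `fes_grid` from [make_fes()] (1-D).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fes <- function(fes, path) {
  stopifnot(inherits(fes, "fes_grid"), length(fes$cv_names) == 1)
  df <- data.frame(fes$centers[[1]], fes$F, fes$error)
  names(df) <- c(fes$cv_names, "free_energy", "error")
  df$error[is.na(df$error)] <- 0
  df <- df[fes$occupied, , drop = FALSE]
  write_colvar(df, path)
}
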