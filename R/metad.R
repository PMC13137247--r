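#' Well-tempered metadynamics bias
#'
#' A history of repulsive Gaussian kernels deposited along one or more
#' collective variables, with the well-tempered damping rule: each new
#' kernel's height is the initial height scaled by
#' `exp(-V(s) / (kB (gamma - 1) T))`, where `V(s)` is the bias already
#' accumulated at the deposition point. The published settings for this
#' system are an initial height of 0.5 kJ/mol, width 0.05 nm, bias factor 15
#' and one deposit per pace interval.
#'
#' @param cv_names character vector of biased collective variables.
#' @param sigma Gaussian width per CV (nm or degrees).
#' @param w0 initial Gaussian height, kJ/mol (> 0). For solute-tempering
#'   replicas pass [replica_scaled_height()] of the base height.
#' @param gamma bias factor (> 1).
#' @param pace deposition interval in sampler sweeps.
#' @return An object of class `metad_bias` with a kernel history (initially
#'   empty): `centers` (matrix, one row per kernel), `heights` (kJ/mol) and
#'   deposit `index`.
#' @examples
#' b <- metad_bias("d1", sigma = 0.05, w0 = 0.5, gamma = 15)
#' b <- deposit(b, 2.0, temperature = 300)
#' evaluate_bias(b, 2.0) # 0.5 at the first kernel's center
#' @export
metad_bias <- function(cv_names = "d1", sigma = 0.05, w0 = 0.5, gamma = 15,
                       pace = 500L) {
  if (!is.numeric(gamma) || gamma <= 1) stop("invalid bias factor: gamma must be > 1")
  stopifnot(w0 > 0, all(sigma > 0), pace >= 1)
  sigma <- rep_len(sigma, length(cv_names))
  structure(
    list(cv_names = cv_names, sigma = sigma, w0 = w0, gamma = gamma,
         pace = as.integer(pace),
         centers = matrix(numeric(0), 0, length(cv_names),
                          dimnames = list(NULL, cv_names)),
         heights = numeric(0), index = integer(0)),
    class = "metad_bias"
  )
}

# rebuild a metad_bias from raw kernel vectors (1-D fast path used by the
# compiled samplers)
metad_bias_from_kernels <- function(centers, heights, template) {
  template$centers <- matrix(centers, ncol = 1,
                             dimnames = list(NULL, template$cv_names))
  template$heights <- heights
  template$index <- seq_along(heights)
  template
}

#' @export
print.metad_bias <- function(x, ...) {
  cat(sprintf(
    "wt-MTD bias on %s: %d kernels, w0 = %g kJ/mol, sigma = %s, gamma = %g\n",
    paste(x$cv_names, collapse = ","), length(x$heights), x$w0,
    paste(x$sigma, collapse = ","), x$gamma))
  invisible(x)
}

#' Well-tempered Gaussian height
#'
#' The damping rule of well-tempered metadynamics: a kernel deposited where
#' bias `current_bias` has already accumulated gets height
#' `w0 * exp(-current_bias / (kB (gamma - 1) T))`. It equals `w0` on
#' untouched ground and decays monotonically as the basin fills; in the
#' `gamma -> Inf` limit the rule reduces to standard metadynamics.
#'
#' @param current_bias accumulated bias at the deposition point, kJ/mol.
#' @param w0 initial height, kJ/mol (> 0).
#' @param gamma bias factor (> 1).
#' @param temperature K.
#' @return Height in (0, w0], kJ/mol.
#' @export
wt_height <- function(current_bias, w0, gamma, temperature) {
  if (!is.numeric(gamma) || gamma <= 1) stop("invalid bias factor: gamma must be > 1")
  stopifnot(w0 > 0, temperature > 0)
  if (is.infinite(gamma)) return(rep_len(w0, length(current_bias)))
  w0 * exp(-current_bias / (kBT(temperature) * (gamma - 1)))
}

#' Evaluate a metadynamics bias
#'
#' Sums the deposited Gaussians at one or more points in CV space:
#' `V(s) = sum_j h_j exp(-sum_d ((s_d - c_jd) / sigma_d)^2 / 2)`.
#'
#' @param bias a [metad_bias()].
#' @param point numeric vector (one point) or matrix/data frame with one
#'   column per biased CV.
#' @return Bias energy (kJ/mol) per point; always >= 0.
#' @export
evaluate_bias <- function(bias, point) {
  stopifnot(inherits(bias, "metad_bias"))
  ncv <- length(bias$cv_names)
  pts <- if (is.null(dim(point))) {
    if (ncv == 1L) matrix(point, ncol = 1) else matrix(point, nrow = 1)
  } else as.matrix(point)
  if (ncol(pts) != ncv)
    stop("dimension mismatch: bias has ", ncv, " CVs, point has ", ncol(pts))
  if (length(bias$heights) == 0) return(numeric(nrow(pts)))
  v <- numeric(nrow(pts))
  for (j in seq_along(bias$heights)) {
    z2 <- rowSums(sweep(sweep(pts, 2, bias$centers[j, ]), 2, bias$sigma, "/")^2)
    v <- v + bias$heights[j] * exp(-0.5 * z2)
  }
  v
}

#' Deposit one well-tempered Gaussian
#'
#' Appends a kernel at `point` with the [wt_height()] implied by the bias
#' already present there. The bias at the deposition point strictly
#' increases.
#'
#' @param bias a [metad_bias()].
#' @param point deposition point in CV space.
#' @param temperature K.
#' @return The updated `metad_bias`.
#' @export
deposit <- function(bias, point, temperature) {
  stopifnot(inherits(bias, "metad_bias"))
  v <- evaluate_bias(bias, point)
  h <- wt_height(v, bias$w0, bias$gamma, temperature)
  bias$centers <- rbind(bias$centers, matrix(point, nrow = 1))
  bias$heights <- c(bias$heights, h)
  bias$index <- c(bias$index, length(bias$heights))
  bias
}

#' Replica-scaled Gaussian height
#'
#' In combined solute-tempering/metadynamics runs the Gaussian height in the
#' replica with Hamiltonian scaling `lambda` is `w / lambda`, so the "hot"
#' replicas (lambda < 1) receive proportionally taller kernels and their
#' flattened minima fill at a matched rate.
#'
#' @param w base Gaussian height, kJ/mol (> 0).
#' @param lambda Hamiltonian scaling factor in (0, 1].
#' @return Scaled height `w / lambda`.
#' @examples
#' replica_scaled_height(0.5, 0.426934) # about 1.171
#' @export
replica_scaled_height <- function(w, lambda) {
  stopifnot(w > 0)
  if (any(lambda <= 0) || any(lambda > 1))
    stop("lambda must be in (0, 1]")
  w / lambda
}

#' Write / read a bias checkpoint table
#'
#' The kernel history is stored as a plain whitespace-delimited table with a
#' `#! FIELDS` header (deposit index, one center and one sigma column per
#' CV, height) and `#! SET` lines for the scalar bias parameters, so a
#' checkpoint round-trips through `read_bias_checkpoint()` with identical
#' values.
#'
#' @param bias a [metad_bias()].
#' @param path file path.
#' @return `write_bias_checkpoint` returns `path` invisibly;
#'   `read_bias_checkpoint` returns a `metad_bias`.
#' @export
write_bias_checkpoint <- function(bias, path) {
  stopifnot(inherits(bias, "metad_bias"))
  cn <- c("index", paste0("center_", bias$cv_names),
          paste0("sigma_", bias$cv_names), "height")
  lines <- c(
    paste("#! FIELDS", paste(cn, collapse = " ")),
    paste("#! SET cv_names", paste(bias$cv_names, collapse = ",")),
    sprintf("#! SET sigma %s", paste(sprintf("%.15g", bias$sigma), collapse = ",")),
    sprintf("#! SET w0 %.15g", bias$w0),
    sprintf("#! SET gamma %.15g", bias$gamma),
    sprintf("#! SET pace %d", bias$pace)
  )
  if (length(bias$heights) > 0) {
    rows <- cbind(bias$index, bias$centers,
                  matrix(bias$sigma, nrow = length(bias$heights),
                         ncol = length(bias$sigma), byrow = TRUE),
                  bias$heights)
    lines <- c(lines, apply(rows, 1, function(r)
      paste(sprintf("%.15g", r), collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bias_checkpoint
#' @export
read_bias_checkpoint <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#! FIELDS"))
    stop("missing '#! FIELDS' header in ", path)
  sets <- lines[startsWith(lines, "#! SET")]
  getset <- function(key) {
    ln <- sets[grepl(paste0("^#! SET ", key, " "), sets)]
    if (length(ln) == 0) stop("missing '#! SET ", key, "' in ", path)
    sub(paste0("^#! SET ", key, " "), "", ln[1])
  }
  cv_names <- strsplit(getset("cv_names"), ",")[[1]]
  body <- lines[!startsWith(lines, "#!")]
  body <- body[nzchar(trimws(body))]
  bias <- metad_bias(cv_names,
                     sigma = as.numeric(strsplit(getset("sigma"), ",")[[1]]),
                     w0 = as.numeric(getset("w0")),
                     gamma = as.numeric(getset("gamma")),
                     pace = as.integer(getset("pace")))
  if (length(body) > 0) {
    vals <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
    ncv <- length(cv_names)
    bias$index <- as.integer(vals[, 1])
    bias$centers <- matrix(vals[, 1 + seq_len(ncv), drop = FALSE], ncol = ncv,
                           dimnames = list(NULL, cv_names))
    bias$sigma <- as.numeric(vals[1, 1 + ncv + seq_len(ncv)])
    bias$heights <- vals[, 2 + 2 * ncv]
  }
  bias
}
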