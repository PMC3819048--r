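#' Spherical-spline parameters
#'
#' Controls the surface-Laplacian (current source density) transform:
#' `m` is the spline flexibility order, `lambda` the smoothing constant added
#' to the diagonal of the interpolation kernel, `n_terms` the truncation of
#' the Legendre series, and `head_radius_cm` the physical radius used to
#' express the Laplacian in \eqn{\mu V/cm^2}.
#'
#' @param m spline flexibility order (integer >= 2; default 4).
#' @param lambda smoothing constant (>= 0; default 1e-5).
#' @param n_terms Legendre series truncation (>= 10; default 50).
#' @param head_radius_cm sphere radius in cm (default 10).
#' @return object of class `spline_params`.
#' @export
spline_params <- function(m = 4, lambda = 1e-5, n_terms = 50, head_radius_cm = 10) {
  stop_if_not(m >= 2, "spline order m must be >= 2")
  stop_if_not(lambda >= 0, "lambda must be >= 0")
  stop_if_not(n_terms >= 10, "n_terms must be >= 10")
  stop_if_not(head_radius_cm > 0, "head_radius_cm must be positive")
  structure(list(m = m, lambda = lambda, n_terms = n_terms,
                 head_radius_cm = head_radius_cm), class = "spline_params")
}

# Legendre series sums evaluated on a matrix of cosines.
# g(x) = (1/4pi) sum (2n+1) / (n(n+1))^m      Pn(x)   (interpolation kernel)
# h(x) = (1/4pi) sum (2n+1) / (n(n+1))^(m-1)  Pn(x)   (negated Laplacian kernel)
# The Laplace-Beltrami operator maps Pn to -n(n+1) Pn, so the surface
# Laplacian of the g-spline is -(1/r^2) * (h-series applied to the same
# coefficients); with CSD defined as minus the Laplacian (current sources
# positive) the CSD kernel is +h / r^2.
legendre_gh <- function(x, m, n_terms) {
  g <- matrix(0, nrow(x), ncol(x))
  h <- g
  Pnm1 <- matrix(1, nrow(x), ncol(x)) # P0
  Pn <- x                             # P1
  for (n in seq_len(n_terms)) {
    nn1 <- n * (n + 1)
    g <- g + (2 * n + 1) / nn1^m * Pn
    h <- h + (2 * n + 1) / nn1^(m - 1) * Pn
    # recurrence: (n+1) P_{n+1} = (2n+1) x P_n - n P_{n-1}
    Pnp1 <- ((2 * n + 1) * x * Pn - n * Pnm1) / (n + 1)
    Pnm1 <- Pn
    Pn <- Pnp1
  }
  list(g = g / (4 * pi), h = h / (4 * pi))
}

#' Build spherical-spline G and H kernel matrices for a montage
#'
#' `G[i, j]` and `H[i, j]` are the truncated Legendre series
#' \eqn{g(\cos\theta_{ij})} and \eqn{h(\cos\theta_{ij})} between electrodes i
#' and j.  G (with `lambda` added to its diagonal) interpolates scalp
#' potentials; H carries the interpolating spline to its surface Laplacian.
#' Both depend only on the montage geometry and are reused across subjects
#' and time points.
#'
#' A warning is recorded if the Legendre tail of the slower-converging
#' h-series is not negligible at `n_terms` (the tail bound is ~n^(3-2m), so
#' the defaults converge comfortably).
#'
#' @param montage a [montage()].
#' @param params a [spline_params()].
#' @return object of class `gh_matrices`: list with `G`, `H`, `params`,
#'   `labels` and `montage_fingerprint` (hash of the rounded positions).
#' @export
build_gh_matrices <- function(montage, params = spline_params()) {
  stopifnot(inherits(montage, "montage"), inherits(params, "spline_params"))
  P <- montage$positions
  cosang <- tcrossprod(P)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  off <- cosang[upper.tri(cosang)]
  if (any(off > 1 - 1e-12)) {
    idx <- which(cosang > 1 - 1e-12 & upper.tri(cosang), arr.ind = TRUE)[1, ]
    stop(sprintf("coincident electrodes: %s and %s",
                 montage$labels[idx[1]], montage$labels[idx[2]]), call. = FALSE)
  }
  gh <- legendre_gh(cosang, params$m, params$n_terms)
  # tail term of the h series at the truncation point, relative to h(1)
  n <- params$n_terms
  tail_term <- (2 * n + 1) / (n * (n + 1))^(params$m - 1) / (4 * pi)
  if (tail_term > 1e-6 * max(abs(diag(gh$h)))) {
    warning(sprintf("Legendre series may not have converged at n_terms = %d (tail term %g)",
                    n, tail_term))
  }
  fp <- paste(sprintf("%.12f", round(P, 12)), collapse = ",")
  structure(list(G = gh$g, H = gh$h, params = params, labels = montage$labels,
                 montage_fingerprint = sum(utf8ToInt(fp) * seq_along(utf8ToInt(fp))) %% 2^31),
            class = "gh_matrices")
}

#' Current-source-density map
#'
#' Channels x samples current density (\eqn{\mu V/cm^2}) for one subject and
#' condition; current sources are positive, sinks negative.
#'
#' @param values channels x samples numeric matrix.
#' @param channels channel labels.
#' @param fs_hz sampling rate.
#' @param window_ms epoch window (ms, half-open).
#' @param subject_id,condition tags.
#' @return object of class `csd_map`.
#' @export
csd_map <- function(values, channels, fs_hz, window_ms, subject_id = NA_character_,
                    condition = NA_character_) {
  values <- as.matrix(values)
  stop_if_not(all(is.finite(values)), "CSD values must be finite")
  stop_if_not(nrow(values) == length(channels), "values rows must match channels")
  rownames(values) <- channels
  structure(list(values = values, channels = as.character(channels),
                 fs_hz = fs_hz, window_ms = window_ms,
                 subject_id = subject_id, condition = condition),
            class = "csd_map")
}

#' @export
print.csd_map <- function(x, ...) {
  cat(sprintf("<csd_map> %s/%s: %d channels x %d samples @ %g Hz, window [%g, %g) ms\n",
              x$subject_id, x$condition, nrow(x$values), ncol(x$values),
              x$fs_hz, x$window_ms[1], x$window_ms[2]))
  invisible(x)
}

#' Transform an ERP to current source density
#'
#' Fits, at every time point, the spherical spline
#' \eqn{u(x) = c_0 + \sum_i c_i g(\cos\theta(x, x_i))} to the scalp
#' potentials with the mean constraint \eqn{\sum_i c_i = 0} (solved as one
#' augmented symmetric system with `lambda` on the G diagonal), then applies
#' the Laplacian kernel H and scales by \eqn{1/r^2} to obtain the CSD in
#' \eqn{\mu V/cm^2} with current sources positive.  The transform is linear
#' in the data and exactly invariant to adding a channel-constant (reference
#' independence).
#'
#' @param erp an [erp()] whose channels match the montage behind `gh` (EOG or
#'   other non-montage channels must be dropped beforehand).
#' @param gh a [build_gh_matrices()] result.
#' @return a [csd_map()].
#' @export
csd_transform <- function(erp, gh) {
  stopifnot(inherits(erp, "erp"), inherits(gh, "gh_matrices"))
  stop_if_not(identical(erp$channels, gh$labels),
              "ERP channels do not match the montage behind the G/H matrices")
  n <- length(gh$labels)
  A <- gh$G + diag(gh$params$lambda, n)
  M <- rbind(cbind(A, 1), c(rep(1, n), 0))
  rhs <- rbind(erp$values, 0)
  sol <- tryCatch(solve(M, rhs),
                  error = function(e) stop("singular smoothed G system: ", conditionMessage(e),
                                           call. = FALSE))
  coefs <- sol[seq_len(n), , drop = FALSE]
  csd <- crossprod(gh$H, coefs) / gh$params$head_radius_cm^2
  csd_map(csd, erp$channels, erp$fs_hz, erp$window_ms, erp$subject_id, erp$condition)
}

#' Difference CSD (scrambled minus comprehension)
#'
#' Pointwise difference between the CSD maps of the two reading conditions
#' for the same subject; the convention throughout is scrambled minus
#' comprehension, so a comprehension-condition source-to-sink flip shows up
#' as a positive difference.
#'
#' @param csd_scrambled,csd_comprehension [csd_map()]s of the same subject
#'   with identical shape and sampling.
#' @return a [csd_map()] with condition `"difference"`.
#' @export
difference_csd <- function(csd_scrambled, csd_comprehension) {
  stopifnot(inherits(csd_scrambled, "csd_map"), inherits(csd_comprehension, "csd_map"))
  stop_if_not(identical(dim(csd_scrambled$values), dim(csd_comprehension$values)) &&
                identical(csd_scrambled$channels, csd_comprehension$channels),
              "CSD maps differ in shape or channels")
  stop_if_not(isTRUE(all.equal(csd_scrambled$fs_hz, csd_comprehension$fs_hz)) &&
                isTRUE(all.equal(csd_scrambled$window_ms, csd_comprehension$window_ms)),
              "CSD maps differ in sampling or window")
  csd_map(csd_scrambled$values - csd_comprehension$values,
          csd_scrambled$channels, csd_scrambled$fs_hz, csd_scrambled$window_ms,
          csd_scrambled$subject_id, "difference")
}
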