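#' Electrode montage
#'
#' A montage is the set of labeled scalp electrodes with idealized positions
#' on a unit sphere, plus the physical head radius (cm) used to express
#' current source densities in \eqn{\mu V/cm^2}.  Coordinates follow the
#' common `.sfp` convention: x to the right, y anterior, z superior.
#'
#' @param labels character vector of channel names (10-10 nomenclature).
#' @param positions numeric matrix, one row per channel, columns x/y/z; every
#'   row must have unit norm (tolerance 1e-9).
#' @param head_radius_cm physical sphere radius in cm (default 10).
#' @return an object of class `montage`: list with `labels`, `positions`
#'   (rownames = labels) and `head_radius_cm`.
#' @seealso [montage_biosemi64()], [read_sfp()], [write_sfp()]
#' @export
montage <- function(labels, positions, head_radius_cm = 10) {
  labels <- as.character(labels)
  positions <- as.matrix(positions)
  stop_if_not(length(labels) >= 2, "a montage needs at least 2 channels")
  stop_if_not(!anyDuplicated(labels), "montage labels must be unique")
  stop_if_not(nrow(positions) == length(labels) && ncol(positions) == 3,
              "positions must be a %d x 3 matrix", length(labels))
  stop_if_not(all(is.finite(positions)), "positions must be finite")
  norms <- sqrt(rowSums(positions^2))
  stop_if_not(all(abs(norms - 1) < 1e-9),
              "all electrode positions must lie on the unit sphere (max |norm-1| = %g)",
              max(abs(norms - 1)))
  stop_if_not(is.numeric(head_radius_cm) && head_radius_cm > 0,
              "head_radius_cm must be positive")
  rownames(positions) <- labels
  colnames(positions) <- c("x", "y", "z")
  structure(list(labels = labels, positions = positions,
                 head_radius_cm = head_radius_cm),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d channels, head radius %.1f cm\n",
              length(x$labels), x$head_radius_cm))
  cat(" ", paste(head(x$labels, 10), collapse = " "),
      if (length(x$labels) > 10) "..." else "", "\n")
  invisible(x)
}

# point on unit sphere from inclination (deg from vertex) and azimuth
# (deg from anterior midline, positive to the right)
sph_point <- function(incl_deg, azim_deg) {
  th <- incl_deg * pi / 180
  ph <- azim_deg * pi / 180
  c(x = sin(th) * sin(ph), y = sin(th) * cos(ph), z = cos(th))
}

# place points at fractions f of the arc from A to B along the circle that
# the sphere cuts in the plane through A, B and mirror(A); for rows through
# the vertex this reduces to a great circle
arc_points <- function(A, B, fracs) {
  Am <- A * c(-1, 1, 1) # left-right mirror
  n <- pracma_cross(A - B, Am - B)
  if (sqrt(sum(n^2)) < 1e-12) { # collinear: fall back to great circle plane
    n <- pracma_cross(A, B)
  }
  n <- n / sqrt(sum(n^2))
  d <- sum(n * A)
  ctr <- n * d
  rho <- sqrt(max(0, 1 - d^2))
  u <- (A - ctr) / sqrt(sum((A - ctr)^2))
  v <- pracma_cross(n, u)
  Bc <- B - ctr
  thB <- atan2(sum(Bc * v), sum(Bc * u))
  t(vapply(fracs, function(f) ctr + rho * (cos(f * thB) * u + sin(f * thB) * v),
           numeric(3)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Idealized 64-channel Biosemi 10-10 montage
#'
#' Generates the 64 scalp sites of the Biosemi-64 layout (extended 10-20 /
#' 10-10 nomenclature, including the frontal-midline site AFz) on an
#' idealized unit sphere.  Construction: the nasion-inion-preauricular plane
#' is the equator; the 20-site circumferential ring (Fpz, Fp2, AF8, ..., Oz,
#' ..., Fp1) sits at 72 degrees inclination with 18-degree azimuth steps;
#' midline sites step 18 degrees along the sagittal arc; lateral sites of the
#' inner rows are spaced at equal arc fractions along the circle through the
#' row's two ring sites and its midline site.  P9/P10 and Iz lie on the
#' equator.
#'
#' @param head_radius_cm physical head radius in cm (default 10).
#' @return a [montage()].
#' @export
montage_biosemi64 <- function(head_radius_cm = 10) {
  pos <- list()
  add <- function(lab, p) pos[[lab]] <<- p

  ring <- c("Fpz", "Fp2", "AF8", "F8", "FT8", "T8", "TP8", "P8", "PO8", "O2",
            "Oz", "O1", "PO7", "P7", "TP7", "T7", "FT7", "F7", "AF7", "Fp1")
  for (i in seq_along(ring)) add(ring[i], sph_point(72, (i - 1) * 18))

  add("Cz", c(0, 0, 1))
  add("FCz", sph_point(18, 0)); add("Fz", sph_point(36, 0))
  add("AFz", sph_point(54, 0))
  add("CPz", sph_point(18, 180)); add("Pz", sph_point(36, 180))
  add("POz", sph_point(54, 180))
  add("Iz", sph_point(90, 180))
  add("P9", sph_point(90, -126)); add("P10", sph_point(90, 126))

  # inner rows: ring end -> midline, sites at equal arc fractions
  row_fill <- function(ring_lab, mid_lab, labs_left_to_mid) {
    k <- length(labs_left_to_mid)
    pts <- arc_points(pos[[ring_lab]], pos[[mid_lab]], seq_len(k) / (k + 1))
    for (i in seq_len(k)) add(labs_left_to_mid[i], pts[i, ])
  }
  row_fill("F7", "Fz", c("F5", "F3", "F1"))
  row_fill("F8", "Fz", c("F6", "F4", "F2"))
  row_fill("FT7", "FCz", c("FC5", "FC3", "FC1"))
  row_fill("FT8", "FCz", c("FC6", "FC4", "FC2"))
  row_fill("T7", "Cz", c("C5", "C3", "C1"))
  row_fill("T8", "Cz", c("C6", "C4", "C2"))
  row_fill("TP7", "CPz", c("CP5", "CP3", "CP1"))
  row_fill("TP8", "CPz", c("CP6", "CP4", "CP2"))
  row_fill("P7", "Pz", c("P5", "P3", "P1"))
  row_fill("P8", "Pz", c("P6", "P4", "P2"))
  row_fill("PO7", "POz", "PO3")
  row_fill("PO8", "POz", "PO4")
  row_fill("Fp1", "AFz", "AF3")
  row_fill("Fp2", "AFz", "AF4")

  labs <- names(pos)
  P <- do.call(rbind, pos)
  P <- P / sqrt(rowSums(P^2)) # absorb rounding
  montage(labs, P, head_radius_cm = head_radius_cm)
}

#' Read / write electrode positions in .sfp format
#'
#' `.sfp` files hold one electrode per line: `label x y z`, whitespace
#' separated.  Positions are renormalized to the unit sphere on read (files
#' may store radii in arbitrary units); `write_sfp` writes unit vectors.
#'
#' @param path file path.
#' @param head_radius_cm head radius to attach on read (default 10).
#' @return `read_sfp` returns a [montage()]; `write_sfp` returns `path`
#'   invisibly.
#' @export
read_sfp <- function(path, head_radius_cm = 10) {
  stop_if_not(file.exists(path), "no such .sfp file: %s", path)
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("label", "x", "y", "z"))
  P <- as.matrix(tab[, c("x", "y", "z")])
  nrm <- sqrt(rowSums(P^2))
  stop_if_not(all(nrm > 0), "zero-length position vector in %s", path)
  montage(tab$label, P / nrm, head_radius_cm = head_radius_cm)
}

#' @rdname read_sfp
#' @param m a [montage()] to write.
#' @export
write_sfp <- function(m, path) {
  stopifnot(inherits(m, "montage"))
  df <- data.frame(label = m$labels, m$positions, check.names = FALSE)
  utils::write.table(format(df, digits = 15), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(path)
}
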