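#' Discrete particle size distribution
#'
#' A set of diameter bins with number densities, characterised by the
#' area-weighted Hansen-Travis moments: effective diameter
#' `D_eff = sum(N d^3) / sum(N d^2)` and effective variance
#' `v_eff = sum(N d^2 (d - D_eff)^2) / (D_eff^2 sum(N d^2))`.
#'
#' @param d diameters, micrometres, strictly positive and increasing.
#' @param N number densities per bin, particles m-3, `>= 0` with at least one
#'   positive bin.
#' @return Object of class `size_distribution` with fields `d`, `N`, `D_eff`,
#'   `v_eff`.
#' @examples
#' size_distribution(c(1, 2), c(1, 1))$D_eff  # 9/5
#' @export
size_distribution <- function(d, N) {
  stopifnot(length(d) == length(N), length(d) >= 1)
  if (any(d <= 0)) stop("diameters must be positive")
  if (is.unsorted(d, strictly = TRUE)) stop("diameters must be increasing")
  if (any(N < 0) || !any(N > 0))
    stop("number densities must be non-negative with at least one positive bin")
  structure(list(d = d, N = N,
                 D_eff = effective_diameter(d, N),
                 v_eff = effective_variance(d, N)),
            class = "size_distribution")
}

#' @rdname size_distribution
#' @export
effective_diameter <- function(d, N) {
  sum(N * d^3) / sum(N * d^2)
}

#' @rdname size_distribution
#' @export
effective_variance <- function(d, N) {
  De <- effective_diameter(d, N)
  sum(N * d^2 * (d - De)^2) / (De^2 * sum(N * d^2))
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("<size_distribution> %d bins, %.3g-%.3g um, D_eff=%.4g um, v_eff=%.4g%s\n",
              length(x$d), min(x$d), max(x$d), x$D_eff, x$v_eff,
              if (isTRUE(attr(x, "chl_normalized"))) " (Chl-normalized)" else ""))
  invisible(x)
}

#' Standard monospecific size distribution for a requested (D_eff, v_eff)
#'
#' Builds the discrete size distribution used for monospecific assemblages:
#' number densities follow the two-parameter standard distribution of
#' size-distribution optics, `n(d) propto d^((1-3b)/b) exp(-d/(a b))`, on a
#' fixed uniform bin grid, with `(a, b)` solved numerically so that the
#' discrete binned moments reproduce the requested effective diameter and
#' effective variance to within 1e-6 (relative).  For `v_eff` below 1e-8 a
#' single delta bin at `D_eff` is returned.
#'
#' @param D_eff requested effective diameter, micrometres, `> 0`.
#' @param v_eff requested effective variance, in `[0, 0.9)`; default 0.6, the
#'   relatively narrow width appropriate for a monospecific culture.
#' @param n_bins number of diameter bins (default 50).
#' @param span optional numeric length 2 giving the bin range in micrometres;
#'   by default `[max(0, D_eff (1 - 8 sqrt(v))), D_eff (1 + 2 sqrt(v) + 4 v)]`.
#' @return A [size_distribution()] whose recomputed moments match the request.
#' @export
make_standard_distribution <- function(D_eff, v_eff = 0.6, n_bins = 50,
                                       span = NULL) {
  stopifnot(D_eff > 0, v_eff >= 0, v_eff < 0.9)
  if (v_eff < 1e-8) {
    return(size_distribution(D_eff, 1))
  }
  if (is.null(span)) {
    lo <- max(0, D_eff * (1 - 8 * sqrt(v_eff)))
    hi <- D_eff * (1 + 2 * sqrt(v_eff) + 4 * v_eff)
  } else {
    lo <- span[1]; hi <- span[2]
  }
  edges <- seq(lo, hi, length.out = n_bins + 1)
  d <- (edges[-1] + edges[-length(edges)]) / 2
  weights <- function(a, b) {
    p <- (1 - 3 * b) / b
    lw <- p * log(d) - d / (a * b)
    exp(lw - max(lw))
  }
  resid <- function(theta) {
    a <- exp(theta[1]); b <- exp(theta[2])
    N <- weights(a, b)
    c(effective_diameter(d, N) / D_eff - 1,
      effective_variance(d, N) / v_eff - 1)
  }
  theta <- log(c(D_eff, v_eff))
  ok <- FALSE
  for (it in 1:80) {
    r0 <- resid(theta)
    if (max(abs(r0)) < 1e-10) { ok <- TRUE; break }
    J <- matrix(0, 2, 2)
    h <- 1e-7
    for (j in 1:2) {
      tp <- theta; tp[j] <- tp[j] + h
      J[, j] <- (resid(tp) - r0) / h
    }
    step <- tryCatch(solve(J, r0), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      stop("parameter-infeasible error: moment solve failed for (D_eff=",
           D_eff, ", v_eff=", v_eff, ")")
    # damped Newton, capped step
    step <- pmin(pmax(step, -1), 1)
    theta <- theta - step
  }
  if (!ok)
    stop("parameter-infeasible error: could not match (D_eff=", D_eff,
         ", v_eff=", v_eff, ") with ", n_bins, " bins on [",
         signif(lo, 4), ", ", signif(hi, 4), "] um")
  size_distribution(d, weights(exp(theta[1]), exp(theta[2])))
}

#' Normalise a size distribution to 1 mg m-3 chlorophyll a
#'
#' Rescales all number densities by a single factor so that the total
#' chlorophyll of the assemblage, `sum(N * V_cell) * c_i`, equals
#' 1 mg m-3; the shape of the distribution is unchanged.  All IOPs computed
#' from a normalised distribution are therefore Chl-a-specific.
#'
#' @param dist a [size_distribution()].
#' @param c_i intracellular Chl-a density, kg m-3, `> 0`.
#' @return The rescaled [size_distribution()], with attributes
#'   `chl_normalized = TRUE` and `c_i`.
#' @export
chl_normalize <- function(dist, c_i) {
  stopifnot(inherits(dist, "size_distribution"), c_i > 0)
  vol <- sum(dist$N * pi / 6 * (dist$d * 1e-6)^3)  # m3 per m3
  if (vol <= 0) stop("total cell volume is zero; cannot normalise")
  out <- size_distribution(dist$d, dist$N / (vol * c_i * 1e6))
  attr(out, "chl_normalized") <- TRUE
  attr(out, "c_i") <- c_i
  out
}

total_chl <- function(dist, c_i) {
  sum(dist$N * pi / 6 * (dist$d * 1e-6)^3) * c_i * 1e6  # mg m-3
}

#' Total assemblage carbon
#'
#' Carbon content of the assemblage, `sum(N * V_cell) * C_i`, in mg C m-3.
#' For a Chl-normalised distribution this is numerically the carbon-to-Chl
#' ratio (mg C per mg Chl a).
#'
#' @param dist a [size_distribution()], typically Chl-normalised.
#' @param C_i intracellular carbon density, kg m-3, `> 0`.
#' @return Total carbon, mg C m-3.
#' @export
total_carbon <- function(dist, C_i) {
  stopifnot(inherits(dist, "size_distribution"), is.finite(C_i), C_i > 0)
  sum(dist$N * pi / 6 * (dist$d * 1e-6)^3) * C_i * 1e6
}

#' Read / write a size distribution as CSV
#'
#' Plain-text interchange format with columns `diameter_um` and
#' `count_per_m3`, e.g. for measured distributions.
#'
#' @param path file path.
#' @return `read_size_distribution` returns a [size_distribution()];
#'   `write_size_distribution` returns the path invisibly.
#' @export
read_size_distribution <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("diameter_um", "count_per_m3")
  if (!all(need %in% names(df)))
    stop("size-distribution file must have columns diameter_um, count_per_m3")
  size_distribution(df$diameter_um, df$count_per_m3)
}

#' @rdname read_size_distribution
#' @param dist a [size_distribution()].
#' @export
write_size_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "size_distribution"))
  df <- data.frame(diameter_um = sprintf("%.17g", dist$d),
                   count_per_m3 = sprintf("%.17g", dist$N))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
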