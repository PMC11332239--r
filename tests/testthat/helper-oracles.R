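# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: plain loops, closed-form colourimetry, and
# direct likelihood maximisation.

# Closed-form sRGB (0-255, D65) -> CIELAB for a single pixel.
oracle_srgb_to_lab <- function(rgb) {
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- as.numeric(M %*% lin)
  wp <- c(0.95047, 1, 1.08883)
  tv <- xyz / wp
  f <- ifelse(tv > (6 / 29)^3, tv^(1 / 3), tv / (3 * (6 / 29)^2) + 4 / 29)
  c(L = 116 * f[2] - 16, a = 500 * (f[1] - f[2]), b = 200 * (f[2] - f[3]))
}

# One-axis bin assignment by explicit scan: half-open [lo, hi), last bin
# closed, out-of-range clamped to the edge bins.
oracle_axis_bin <- function(x, breaks) {
  nb <- length(breaks) - 1L
  if (x < breaks[1]) return(1L)
  for (j in seq_len(nb)) {
    if (x < breaks[j + 1]) return(j)
    if (j == nb && x <= breaks[j + 1]) return(nb)
  }
  nb
}

# Brute-force per-pixel binning of a Lab matrix into a 3-D count array.
oracle_bin_counts <- function(lab, grid) {
  counts <- array(0L, dim = c(grid$a_bins, grid$b_bins, grid$L_bins))
  for (i in seq_len(nrow(lab))) {
    ia <- oracle_axis_bin(lab[i, 2], grid$a_breaks)
    ib <- oracle_axis_bin(lab[i, 3], grid$b_breaks)
    iL <- oracle_axis_bin(lab[i, 1], grid$L_breaks)
    counts[ia, ib, iL] <- counts[ia, ib, iL] + 1L
  }
  counts
}

# Convert a color_histogram to the same 3-D count array for comparison.
hist_to_counts <- function(hist, grid) {
  counts <- array(0L, dim = c(grid$a_bins, grid$b_bins, grid$L_bins))
  for (i in seq_len(nrow(hist))) {
    counts[hist$a_bin[i], hist$b_bin[i], hist$L_bin[i]] <- hist$count[i]
  }
  counts
}

# Direct ML fit of fixed-effects beta regression (logit link) by optim;
# independent of the package's optimiser and objective code.
oracle_beta_ml <- function(X, y, maxit = 2000) {
  nll <- function(par) {
    eta <- drop(X %*% par[seq_len(ncol(X))])
    mu <- 1 / (1 + exp(-eta))
    phi <- exp(par[ncol(X) + 1])
    val <- -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
    if (is.finite(val)) val else 1e10
  }
  start <- c(rep(0, ncol(X)), log(10))
  o <- stats::optim(start, nll, method = "BFGS",
                    control = list(maxit = maxit, reltol = 1e-14))
  list(beta = o$par[seq_len(ncol(X))], phi = exp(o$par[ncol(X) + 1]),
       nll = o$value)
}

# Small standardised trait panel on a taxonomy, for GLMM tests.
make_sim_panel <- function(tax, vars, seed) {
  set.seed(seed)
  for (v in vars) tax[[v]] <- rnorm(nrow(tax))
  tax
}
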