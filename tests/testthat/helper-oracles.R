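# Shared fixtures and independent oracles, built in code.

# Partition-function object with an analytic T(q) on a grid.
analytic_pf <- function(Tfun, q = seq(-5, 5, by = 0.1)) {
  structure(list(table = tibble::tibble(q = q, T = Tfun(q),
                                        intercept = 0, r2 = 1,
                                        n_scales = 5L),
                 scale_range = c(3L, 7L), q_grid = q, J = 10L,
                 wavelet = "db6", n_orig = NA_integer_),
            class = "mf_pf")
}

# Spectrum sampled from an explicit f(alpha) curve; q decreasing in alpha.
analytic_spectrum <- function(alpha, f) {
  ord <- order(alpha, decreasing = TRUE)   # alpha decreases as q increases
  q <- seq_along(alpha) - which.max(f[ord])
  mfspectra:::new_mf_spectrum(q = q * 0.1, alpha = alpha[ord], f = f[ord])
}

# Moments object with prescribed log2_S values per (level, q).
manual_moments <- function(levels, q_grid, log2_S_matrix, J = max(levels) + 3L) {
  stopifnot(nrow(log2_S_matrix) == length(levels),
            ncol(log2_S_matrix) == length(q_grid))
  tab <- tibble::tibble(
    level = rep(levels, times = length(q_grid)),
    q = rep(q_grid, each = length(levels)),
    log2_S = as.vector(log2_S_matrix),
    n_retained = 8L)
  structure(tab, class = c("mf_moments", class(tibble::tibble())),
            q_grid = q_grid, J = J, eps_floor = 1e-12,
            wavelet = "db6", n_orig = NA_integer_)
}

# Brute-force nested-least-squares F test for one term of a main-effects
# model: F = ((RSS_r - RSS_f)/ddf) / (RSS_f/df_res), fitted via explicit
# model matrices (independent of the package's drop1 route).
oracle_anova_F <- function(d, term) {
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  mm <- function(formula) {
    X <- stats::model.matrix(formula, data = d)
    fit <- stats::lm.fit(X, d$y)
    list(rss = sum(fit$residuals^2), p = fit$rank)
  }
  full <- mm(y ~ group + period + time)
  red <- mm(stats::reformulate(setdiff(c("group", "period", "time"), term),
                               response = "y"))
  ddf <- full$p - red$p
  df_res <- nrow(d) - full$p
  Fv <- ((red$rss - full$rss) / ddf) / (full$rss / df_res)
  list(F = Fv, df = ddf, df_res = df_res,
       p = stats::pf(Fv, ddf, df_res, lower.tail = FALSE))
}

# Box-counting partition exponents of a cascade measure: slope of
# log2 sum(mass^q) over dyadic aggregation levels.
oracle_box_tau <- function(signal, q) {
  mass <- signal / sum(signal)
  depths <- integer(0); ls <- numeric(0)
  m <- as.integer(round(log2(length(mass))))
  cur <- mass
  for (depth in m:1) {
    ls <- c(ls, log2(sum(cur^q)))
    depths <- c(depths, depth)
    cur <- cur[seq(1, length(cur), by = 2)] + cur[seq(2, length(cur), by = 2)]
  }
  -unname(coef(lm(ls ~ depths))[2])
}

# Cohort-like paired signals sharing one envelope, used for the group
# ordering properties.
paired_group_signals <- function(seed, n = 4096,
                                 config = generator_config()) {
  skel <- mfspectra:::envelope_skeleton(config, 999L)
  env <- mfspectra:::envelope_signal(skel, n, skel$amp)
  cal <- mfspectra:::.sm_calibration
  mk <- function(target, s) {
    h <- (target - cal[["intercept"]]) / cal[["slope"]]
    tex <- cumsum(simulate_fgn(n, h, s))
    config$envelope_scale * env + tex / sd(tex)
  }
  list(high = mk(config$h_high, seed), low = mk(config$h_low, seed + 50000L))
}

descriptors_of <- function(x, ...) {
  suppressMessages(
    mf_descriptors(multifractal_spectrum(x), auto_relax = TRUE,
                   relax_floor = 1e-4, ...))
}

broadness_or_na <- function(x) {
  tryCatch(descriptors_of(x)$B, mfspectra_error_descriptor = function(e) NA_real_)
}
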