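#' Assemble a two-sample MR instrument table
#'
#' @param snp instrument identifiers.
#' @param beta_exposure,se_exposure per-variant effect and SE on the
#'   exposure.
#' @param beta_outcome,se_outcome per-variant effect and SE on the
#'   outcome, harmonised to the same effect allele.
#' @return Data frame of class `mr_instruments`.
#' @export
mr_instruments <- function(snp, beta_exposure, se_exposure,
                           beta_outcome, se_outcome) {
  n <- length(snp)
  rec <- function(x) if (length(x) == 1L) rep(x, n) else x
  beta_exposure <- rec(beta_exposure); se_exposure <- rec(se_exposure)
  beta_outcome <- rec(beta_outcome); se_outcome <- rec(se_outcome)
  stopifnot(length(beta_exposure) == n, length(se_exposure) == n,
            length(beta_outcome) == n, length(se_outcome) == n)
  if (any(se_exposure <= 0) || any(se_outcome <= 0))
    stop("standard errors must be positive")
  structure(data.frame(snp = as.character(snp),
                       beta_exposure = beta_exposure,
                       se_exposure = se_exposure,
                       beta_outcome = beta_outcome,
                       se_outcome = se_outcome,
                       stringsAsFactors = FALSE),
            class = c("mr_instruments", "data.frame"))
}

#' Read an instrument file
#'
#' Tab-delimited with columns `SNP`, `beta_exp`, `se_exp`, `beta_out`,
#' `se_out`.
#'
#' @param path file path.
#' @return An [mr_instruments()] table.
#' @export
read_instruments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("SNP", "beta_exp", "se_exp", "beta_out", "se_out")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("instrument file missing column(s): ", paste(miss, collapse = ", "))
  mr_instruments(df$SNP, df$beta_exp, df$se_exp, df$beta_out, df$se_out)
}

#' Harmonise exposure and outcome summary statistics
#'
#' Thin pre-step: variants are matched by id, outcome effects are
#' flipped when the outcome's effect allele equals the exposure's other
#' allele, unmatched allele pairs are dropped, and strand-ambiguous
#' (palindromic A/T, C/G) variants with minor-allele frequency above
#' `maf_threshold` are removed because their strand cannot be resolved.
#'
#' @param exposure,outcome data frames from [read_sumstats()].
#' @param maf_threshold palindromic variants with MAF above this are
#'   dropped (default 0.42).
#' @return An [mr_instruments()] table.
#' @export
mr_harmonise <- function(exposure, outcome, maf_threshold = 0.42) {
  m <- merge(exposure, outcome, by = "snp", suffixes = c("_exp", "_out"))
  if (nrow(m) == 0) stop("no shared variants")
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  pal <- m$ea_exp == comp[m$oa_exp]
  maf <- pmin(m$eaf_exp, 1 - m$eaf_exp)
  drop_pal <- pal & maf > maf_threshold
  same <- m$ea_out == m$ea_exp & m$oa_out == m$oa_exp
  flip <- m$ea_out == m$oa_exp & m$oa_out == m$ea_exp
  keep <- (same | flip) & !drop_pal
  m <- m[keep, , drop = FALSE]
  b_out <- ifelse(m$ea_out == m$ea_exp, m$beta_out, -m$beta_out)
  mr_instruments(m$snp, m$beta_exp, m$se_exp, b_out, m$se_out)
}

#' Wald ratio of a single instrument
#'
#' `beta_outcome / beta_exposure` with first-order standard error
#' `se_outcome / |beta_exposure|`.  Invariant to a simultaneous sign
#' flip of both effects.
#'
#' @param instrument one-row [mr_instruments()] (or a list with the same
#'   fields).
#' @return List with `estimate` and `se`.
#' @export
wald_ratio <- function(instrument) {
  if (instrument$beta_exposure == 0)
    stop("Wald ratio undefined: beta_exposure is zero")
  list(estimate = instrument$beta_outcome / instrument$beta_exposure,
       se = instrument$se_outcome / abs(instrument$beta_exposure))
}

# per-instrument ratio estimates and weights.
# first-order:  w = beta_exp^2 / se_out^2 (NOME approximation);
# second-order: adds the exposure-side variance term, the modified
# weighting used for heterogeneity diagnosis and pruning.
ratio_weights <- function(ins, weights = c("first", "second")) {
  weights <- match.arg(weights)
  ratio <- ins$beta_outcome / ins$beta_exposure
  v1 <- ins$se_outcome^2 / ins$beta_exposure^2
  v <- if (weights == "first") v1 else
    v1 + ins$beta_outcome^2 * ins$se_exposure^2 / ins$beta_exposure^4
  list(ratio = ratio, w = 1 / v)
}

mr_estimate <- function(method, estimate, se, p, n_used, excluded = character(0),
                        intercept = NA_real_, intercept_se = NA_real_,
                        Q = NA_real_) {
  structure(list(method = method, estimate = estimate, se = se, p = p,
                 intercept = intercept, intercept_se = intercept_se,
                 n_instruments_used = n_used, excluded_snps = excluded,
                 Q = Q),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR %s: estimate=%.4g se=%.4g p=%.3g (n=%d)\n",
              x$method, x$estimate, x$se, x$p, x$n_instruments_used))
  if (!is.na(x$intercept))
    cat(sprintf("  intercept=%.4g se=%.4g\n", x$intercept, x$intercept_se))
  invisible(x)
}

#' Inverse-variance weighted MR estimate
#'
#' Inverse-variance weighted mean of per-variant Wald ratios,
#' equivalently a zero-intercept weighted regression of outcome on
#' exposure effects.  When Cochran's Q exceeds its degrees of freedom
#' the standard error is inflated multiplicatively by
#' `sqrt(Q / (n - 1))` (multiplicative random-effects model); it is
#' never deflated.  With a single instrument the estimate reduces to the
#' Wald ratio (use [wald_ratio()] directly).
#'
#' @param instruments an [mr_instruments()] table with >= 2 rows.
#' @param weights `"first"`- or `"second"`-order ratio weights.
#' @return An `mr_estimate`.
#' @export
mr_ivw <- function(instruments, weights = "first") {
  if (nrow(instruments) < 2)
    stop("IVW needs >= 2 instruments; for one instrument use wald_ratio()")
  rw <- ratio_weights(instruments, weights)
  est <- sum(rw$w * rw$ratio) / sum(rw$w)
  Q <- sum(rw$w * (rw$ratio - est)^2)
  phi <- max(1, Q / (nrow(instruments) - 1))
  se <- sqrt(phi / sum(rw$w))
  mr_estimate("ivw", est, se, 2 * stats::pnorm(-abs(est / se)),
              nrow(instruments), Q = Q)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a
#' free intercept, all exposure effects oriented positive.  The slope is
#' the causal estimate; the intercept estimates mean directional
#' pleiotropy.  Standard errors use a multiplicative residual dispersion
#' floored at 1; P-values are normal-based.
#'
#' @param instruments an [mr_instruments()] table with >= 3 rows.
#' @param weights `"first"`- or `"second"`-order outcome weights.
#' @return An `mr_estimate` with `intercept` and `intercept_se` filled.
#' @export
mr_egger <- function(instruments, weights = "first") {
  n <- nrow(instruments)
  if (n < 3) stop("MR-Egger needs >= 3 instruments")
  flip <- sign(instruments$beta_exposure)
  bx <- instruments$beta_exposure * flip
  by <- instruments$beta_outcome * flip
  w <- if (weights == "first") 1 / instruments$se_outcome^2 else
    1 / (instruments$se_outcome^2 +
           instruments$beta_outcome^2 * instruments$se_exposure^2 /
           instruments$beta_exposure^2)
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  cf <- solve(XtWX, crossprod(X, w * by))
  r <- by - X %*% cf
  phi <- max(1, sum(w * r^2) / (n - 2))
  vc <- phi * solve(XtWX)
  se <- sqrt(diag(vc))
  mr_estimate("egger", cf[2], se[2], 2 * stats::pnorm(-abs(cf[2] / se[2])),
              n, intercept = cf[1], intercept_se = se[1],
              Q = sum(w * r^2))
}

# weighted median by linear interpolation of the standardized
# cumulative weights at 50%
weighted_median_value <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(x[1])
  if (s[length(s)] <= 0.5) return(x[length(x)])
  stats::approx(s, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimate
#'
#' Median of per-variant Wald ratios weighted by inverse ratio variance
#' (weighted-percentile interpolation at 50%); consistent when less than
#' half the weight comes from invalid instruments.  The penalised
#' variant down-weights each instrument by `min(1, penalty * q_p)` where
#' `q_p` is the chi-square(1) upper-tail probability of its Cochran's Q
#' contribution about the unpenalised estimate.  The standard error
#' comes from a seeded parametric bootstrap.
#'
#' @param instruments an [mr_instruments()] table with >= 3 rows.
#' @param penalised apply the heterogeneity penalty.
#' @param penalty penalisation constant (default 20, the usual
#'   convention).
#' @param n_boot parametric-bootstrap draws for the SE; `0` skips the
#'   bootstrap (`se` and `p` are `NA`).
#' @param seed bootstrap seed.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(instruments, penalised = FALSE, penalty = 20,
                               n_boot = 2000, seed = 1L) {
  if (nrow(instruments) < 3) stop("weighted median needs >= 3 instruments")
  point <- function(ins) {
    rw <- ratio_weights(ins, "first")
    w <- rw$w
    if (penalised) {
      est0 <- weighted_median_value(rw$ratio, w)
      q <- w * (rw$ratio - est0)^2
      w <- w * pmin(1, penalty * stats::pchisq(q, df = 1, lower.tail = FALSE))
    }
    weighted_median_value(rw$ratio, w)
  }
  est <- point(instruments)
  se <- p <- NA_real_
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    boot <- vapply(seq_len(n_boot), function(b) {
      ins <- instruments
      ins$beta_exposure <- rnorm(nrow(ins), instruments$beta_exposure,
                                 instruments$se_exposure)
      ins$beta_outcome <- rnorm(nrow(ins), instruments$beta_outcome,
                                instruments$se_outcome)
      point(ins)
    }, 0)
    se <- stats::sd(boot)
    p <- 2 * stats::pnorm(-abs(est / se))
  }
  mr_estimate(if (penalised) "penalised_weighted_median" else "weighted_median",
              est, se, p, nrow(instruments))
}

#' Cochran's Q heterogeneity of the Wald ratios
#'
#' `q_i = w_i (ratio_i - estimate)^2`, summing to the total Q, which
#' follows a chi-square(n - 1) distribution when all instruments are
#' valid.  Weights match the estimator being diagnosed.
#'
#' @param instruments an [mr_instruments()] table with >= 2 rows.
#' @param estimate reference causal estimate; defaults to the IVW
#'   estimate under the same weights.
#' @param weights `"first"` or `"second"` order.
#' @return List with per-instrument `q`, total `Q`, `df` and the
#'   `estimate` used.
#' @export
mr_cochran_q <- function(instruments, estimate = NULL,
                         weights = c("second", "first")) {
  weights <- match.arg(weights)
  if (nrow(instruments) < 2) stop("need >= 2 instruments")
  rw <- ratio_weights(instruments, weights)
  if (is.null(estimate)) estimate <- sum(rw$w * rw$ratio) / sum(rw$w)
  q <- rw$w * (rw$ratio - estimate)^2
  list(q = setNames(q, instruments$snp), Q = sum(q),
       df = nrow(instruments) - 1, estimate = estimate)
}

#' Prune instruments by their Cochran's Q contribution
#'
#' Iteratively removes pleiotropic outliers: at each step the IVW
#' estimate and per-instrument Q contributions are recomputed on the
#' current set of size `n`, and the single largest contribution is
#' dropped if it exceeds the Bonferroni-corrected chi-square threshold
#' `qchisq(1 - 0.05/n, 1)`; iteration stops when no contribution
#' exceeds it.  Deterministic; by default the modified second-order
#' ratio weights are used.
#'
#' @param instruments an [mr_instruments()] table with >= 3 rows.
#' @param weights weighting strategy, `"second"` (default) or
#'   `"first"`.
#' @param alpha family-wise level of the Bonferroni rule.
#' @return List with `retained` (an `mr_instruments` table) and
#'   `excluded` (SNP ids in removal order).
#' @export
mr_prune_instruments <- function(instruments, weights = "second",
                                 alpha = 0.05) {
  if (nrow(instruments) < 3) stop("pruning needs >= 3 instruments")
  excluded <- character(0)
  cur <- instruments
  repeat {
    n <- nrow(cur)
    if (n < 2)
      stop("pruning removed too many instruments; excluded so far: ",
           paste(excluded, collapse = ", "))
    qq <- mr_cochran_q(cur, weights = weights)
    thr <- stats::qchisq(1 - alpha / n, df = 1)
    worst <- which.max(qq$q)
    if (qq$q[worst] <= thr) break
    excluded <- c(excluded, cur$snp[worst])
    cur <- cur[-worst, , drop = FALSE]
  }
  list(retained = cur, excluded = excluded)
}

#' Run the full MR toolkit on one instrument set
#'
#' Optional Q-based pruning followed by the requested estimators.
#'
#' @param instruments an [mr_instruments()] table.
#' @param methods subset of `c("ivw", "egger", "wm", "pwm")`.
#' @param prune apply [mr_prune_instruments()] first.
#' @param n_boot bootstrap draws for the median SEs.
#' @param seed bootstrap seed.
#' @return List with `estimates` (named list of `mr_estimate`), `Q`
#'   diagnostics of the analysed set, and `excluded_snps`.
#' @export
mr_run <- function(instruments, methods = c("ivw", "egger", "wm", "pwm"),
                   prune = TRUE, n_boot = 2000, seed = 1L) {
  excluded <- character(0)
  if (prune) {
    pr <- mr_prune_instruments(instruments)
    instruments <- pr$retained
    excluded <- pr$excluded
  }
  est <- list()
  if ("ivw" %in% methods) est$ivw <- mr_ivw(instruments)
  if ("egger" %in% methods) est$egger <- mr_egger(instruments)
  if ("wm" %in% methods)
    est$weighted_median <- mr_weighted_median(instruments, FALSE,
                                              n_boot = n_boot, seed = seed)
  if ("pwm" %in% methods)
    est$penalised_weighted_median <-
      mr_weighted_median(instruments, TRUE, n_boot = n_boot, seed = seed)
  for (e in names(est)) est[[e]]$excluded_snps <- excluded
  list(estimates = est, Q = mr_cochran_q(instruments),
       excluded_snps = excluded)
}

#' Simulate a two-sample MR instrument set
#'
#' Standard generative model for validation: per-variant exposure
#' effects `gamma_j ~ U(gamma_range)`, observed with error `se_exposure`;
#' outcome effects `theta * gamma_j + alpha_j` observed with error
#' `se_outcome`, where `alpha_j` is the pleiotropic effect (zero for
#' valid instruments, `constant_pleiotropy` for the first `n_invalid`).
#' Defaults describe a well-conditioned two-sample design: exposure
#' effects estimated in a much larger study than the outcome
#' (`se_exposure << se_outcome`) with enough spread in instrument
#' strength for the Egger slope to be identifiable without noticeable
#' regression dilution.
#'
#' @param n number of instruments.
#' @param theta true causal effect.
#' @param gamma_range range of true exposure effects.
#' @param se_exposure,se_outcome observation SEs.
#' @param n_invalid number of pleiotropic instruments.
#' @param constant_pleiotropy directional pleiotropy added to invalid
#'   instruments' outcome effects.
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @return An [mr_instruments()] table.
#' @export
simulate_instruments <- function(n = 50, theta = 0.5,
                                 gamma_range = c(0.05, 0.25),
                                 se_exposure = 0.002, se_outcome = 0.05,
                                 n_invalid = 0, constant_pleiotropy = 0,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  gamma <- runif(n, gamma_range[1], gamma_range[2])
  alpha <- numeric(n)
  if (n_invalid > 0) alpha[seq_len(n_invalid)] <- constant_pleiotropy
  mr_instruments(
    sprintf("snp%03d", seq_len(n)),
    rnorm(n, gamma, se_exposure), rep(se_exposure, n),
    rnorm(n, theta * gamma + alpha, se_outcome), rep(se_outcome, n))
}
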