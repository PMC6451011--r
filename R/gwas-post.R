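#' Read GWAS summary statistics
#'
#' Tab-delimited input with required columns `SNP`, `CHR`, `BP` (GRCh37,
#' 1-based), `EA`, `OA`, `FREQ`, `BETA`, `SE`, `P`; optional `TRAIT` and
#' `GENE` columns are kept.  P-values in scientific shorthand
#' (`"2E-35"`) or decimal form are accepted; a `log10_p` column is added
#' so thresholding survives values far below double underflow of
#' intermediate arithmetic.  Malformed rows are reported with their line
#' numbers.
#'
#' @param path tab-delimited file.
#' @return Data frame of validated rows.
#' @export
read_sumstats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  need <- c("SNP", "CHR", "BP", "EA", "OA", "FREQ", "BETA", "SE", "P")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sumstats file missing column(s): ", paste(miss, collapse = ", "))
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- data.frame(
    trait = if ("TRAIT" %in% names(df)) df$TRAIT else NA_character_,
    snp = df$SNP, chr = df$CHR, bp = num(df$BP),
    ea = toupper(df$EA), oa = toupper(df$OA),
    eaf = num(df$FREQ), beta = num(df$BETA), se = num(df$SE),
    p = num(df$P),
    gene = if ("GENE" %in% names(df)) df$GENE else NA_character_,
    stringsAsFactors = FALSE)
  # exact log10 from mantissa/exponent, robust to tiny P
  m <- regmatches(df$P, regexec("^\\s*([0-9.]+)[eE]([+-]?[0-9]+)\\s*$", df$P))
  out$log10_p <- ifelse(
    lengths(m) == 3,
    vapply(m, function(g) if (length(g) == 3)
      log10(as.numeric(g[2])) + as.numeric(g[3]) else NA_real_, 0),
    log10(out$p))
  line <- seq_len(nrow(out)) + 1L          # header is line 1
  bad <- which(is.na(out$p) | out$p <= 0 | out$p > 1)
  if (length(bad))
    stop("unparseable or out-of-range P at line(s) ",
         paste(utils::head(line[bad], 5), collapse = ", "), " of ", path)
  bad <- which(is.na(out$eaf) | out$eaf <= 0 | out$eaf >= 1 |
                 is.na(out$se) | out$se <= 0 | is.na(out$beta) |
                 out$ea == out$oa)
  if (length(bad))
    stop("invalid row(s) at line(s) ",
         paste(utils::head(line[bad], 5), collapse = ", "), " of ", path,
         " (need 0 < FREQ < 1, SE > 0, EA != OA)")
  out
}

#' Path to the packaged 47-row association table
#'
#' A transcription of the discovery lead-SNP table (eight
#' accelerometer-derived sleep traits, GRCh37 coordinates, effects on
#' the inverse-normal trait scale).
#'
#' @return File path usable with [read_sumstats()].
#' @export
table3_path <- function() {
  system.file("extdata", "table3.tsv", package = "actisleep", mustWork = TRUE)
}

#' Count associations below a P-value threshold
#'
#' Strict `<` comparison on the log10 scale.
#'
#' @param hits data frame from [read_sumstats()].
#' @param p_threshold threshold in (0, 1).
#' @param trait optional trait filter (exact match on the `trait`
#'   column).
#' @return Integer count.
#' @export
count_below <- function(hits, p_threshold, trait = NULL) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  if (!is.null(trait)) hits <- hits[hits$trait == trait, , drop = FALSE]
  sum(hits$log10_p < log10(p_threshold))
}

#' Variance explained by a variant on a standardised trait
#'
#' `2 f (1 - f) beta^2` for effect-allele frequency `f` and per-allele
#' effect `beta` in SD units of the inverse-normal trait.  Vectorised;
#' per-trait totals are sums over that trait's lead SNPs.
#'
#' @param eaf effect-allele frequency.
#' @param beta per-allele effect, SD units.
#' @return Fraction of trait variance (not percent).
#' @export
variance_explained <- function(eaf, beta) 2 * eaf * (1 - eaf) * beta^2

#' Align summary statistics to the trait-increasing allele
#'
#' Rows with negative beta get alleles swapped, `eaf -> 1 - eaf` and
#' `beta -> -beta`; `se` and `p` are unchanged.  Idempotent.
#'
#' @param hits data frame from [read_sumstats()].
#' @return Data frame with all `beta >= 0`.
#' @export
align_to_increasing <- function(hits) {
  flip <- hits$beta < 0
  tmp <- hits$ea[flip]
  hits$ea[flip] <- hits$oa[flip]
  hits$oa[flip] <- tmp
  hits$eaf[flip] <- 1 - hits$eaf[flip]
  hits$beta[flip] <- -hits$beta[flip]
  hits
}

#' Exact binomial sign-consistency test
#'
#' Tail probability that at least `k` of `n` independent signs agree
#' under the null of no consistency (p = 0.5).  One-sided (default) is
#' `P(X >= k)`; two-sided doubles the smaller tail by symmetry, capped
#' at 1.
#'
#' @param k number of directionally consistent effects.
#' @param n total effects compared.
#' @param sided `"one"` or `"two"`.
#' @return P-value.
#' @export
sign_consistency_test <- function(k, n, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (n == 0) stop("n must be positive")
  stopifnot(k >= 0, k <= n)
  one <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  if (sided == "one") one else min(1, 2 * min(one, stats::pbinom(k, n, 0.5)))
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Weights `1/se^2`; pooled `beta = sum(w b) / sum(w)`,
#' `se = 1/sqrt(sum(w))`, two-sided Wald P from the normal distribution,
#' plus Cochran's Q across studies.
#'
#' @param betas,ses study effects and standard errors (`ses > 0`).
#' @return List of class `meta_result`: `beta`, `se`, `p`, `n_studies`,
#'   `Q`.
#' @export
ivw_meta <- function(betas, ses) {
  stopifnot(length(betas) == length(ses), length(betas) >= 1, all(ses > 0))
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  structure(list(beta = beta, se = se,
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 n_studies = length(betas),
                 Q = sum(w * (betas - beta)^2)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta: beta=%.4g se=%.4g p=%.3g (n=%d, Q=%.3g)\n",
              x$beta, x$se, x$p, x$n_studies, x$Q))
  invisible(x)
}

#' Combined effect of a trait's lead SNPs in replication data
#'
#' Fixed-effect inverse-variance pool across the lead SNPs of one trait
#' using their replication meta-analysed effects, all aligned to the
#' discovery trait-increasing allele; yields one overall beta/se/P per
#' trait.
#'
#' @param betas,ses per-SNP replication effects and SEs, aligned.
#' @param discovery_betas optional discovery effects; if supplied, any
#'   negative value signals unaligned input and is an error.
#' @return A `meta_result` (see [ivw_meta()]).
#' @export
combined_effect_test <- function(betas, ses, discovery_betas = NULL) {
  if (length(betas) < 2) stop("need >= 2 lead SNPs for a combined effect")
  if (!is.null(discovery_betas) && any(discovery_betas < 0))
    stop("discovery effects must be aligned to the trait-increasing allele")
  ivw_meta(betas, ses)
}

#' Genomic-control inflation factor
#'
#' Median association chi-square (1 d.f. quantile of `1 - p`) divided by
#' the null median `qchisq(0.5, 1)` (0.4549 to 4 d.p.; the exact
#' constant is used).
#'
#' @param p_values vector of P-values in (0, 1].
#' @return Lambda GC.
#' @export
lambda_gc <- function(p_values) {
  stopifnot(length(p_values) >= 1, all(p_values > 0), all(p_values <= 1))
  stats::median(stats::qchisq(p_values, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Convert an SD-scale effect to minutes
#'
#' `beta_sd * trait_sd_hours * 60`: the per-allele effect of a variant
#' on a duration/timing trait, re-expressed from inverse-normal SD units
#' into minutes using the trait's original-scale SD.
#'
#' @param beta_sd effect in SD units.
#' @param trait_sd_hours trait standard deviation in hours (> 0).
#' @return Effect in minutes.
#' @export
effect_in_minutes <- function(beta_sd, trait_sd_hours) {
  stopifnot(all(trait_sd_hours > 0))
  beta_sd * trait_sd_hours * 60
}
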