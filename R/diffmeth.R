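# Per-case differential methylation versus the control group: TMM-style
# library normalization, moment dispersion estimation from controls, and a
# conditional negative-binomial exact test with Benjamini-Hochberg
# adjustment.

#' TMM-style effective library sizes
#'
#' Computes a scaling factor per sample as the trimmed mean of log2 count
#' ratios against a reference sample (the one with the largest library),
#' trimming 30% of the log-ratios and 5% of the abundances (symmetric
#' tails).  Factors are centred to geometric mean 1; the effective library
#' size is the raw size times the factor.
#'
#' @param mat a `region_count_matrix`.
#' @param logratio_trim total fraction of log-ratios trimmed (default 0.3).
#' @param abundance_trim total fraction of abundances trimmed (default
#'   0.05).
#' @return list with `factors` and `effective_sizes`, both named by sample.
#' @export
normalize_libraries <- function(mat, logratio_trim = 0.3,
                                abundance_trim = 0.05) {
  stopifnot(inherits(mat, "region_count_matrix"))
  counts <- mat$counts
  lib <- mat$library_sizes
  if (ncol(counts) < 2) stop("normalization requires at least two samples")
  if (any(colSums(counts) == 0)) {
    stop("cannot normalize a sample with all-zero counts")
  }
  ref <- which.max(lib)
  f <- vapply(seq_len(ncol(counts)), function(s) {
    x <- counts[, s]
    r <- counts[, ref]
    keep <- x > 0 & r > 0
    if (!any(keep)) return(1)
    px <- x[keep] / lib[s]
    pr <- r[keep] / lib[ref]
    M <- log2(px / pr)
    A <- 0.5 * log2(px * pr)
    qm <- quantile(M, c(logratio_trim / 2, 1 - logratio_trim / 2))
    qa <- quantile(A, c(abundance_trim / 2, 1 - abundance_trim / 2))
    sel <- M >= qm[1] & M <= qm[2] & A >= qa[1] & A <= qa[2]
    if (!any(sel)) sel <- rep(TRUE, length(M))
    2^mean(M[sel])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  list(factors = f, effective_sizes = lib * f)
}

#' Estimate a common NB dispersion from the control samples
#'
#' Method-of-moments: control counts are scaled to a common effective
#' library size; per region, `phi_i = max(0, (s^2 - m) / m^2)`; the common
#' dispersion is the median over regions with scaled mean at least
#' `min_mean`, floored at `floor`.  Only control columns are used because
#' case columns carry true effects and single-case groups admit no
#' within-group dispersion.
#'
#' @param mat a `region_count_matrix`.
#' @param controls control sample ids (at least 3).
#' @param effective_sizes optional named effective sizes (defaults to raw
#'   library sizes).
#' @param min_mean minimum scaled mean for a region to inform the common
#'   estimate (default 10).
#' @param floor lower bound on the returned dispersion (default 1e-4).
#' @return list with `phi` (common dispersion) and `per_region_phi`.
#' @export
estimate_dispersion <- function(mat, controls, effective_sizes = NULL,
                                min_mean = 10, floor = 1e-4) {
  stopifnot(inherits(mat, "region_count_matrix"))
  if (length(controls) < 3) {
    stop("dispersion estimation requires at least 3 controls")
  }
  stopifnot(all(controls %in% mat$samples))
  if (is.null(effective_sizes)) effective_sizes <- mat$library_sizes
  es <- effective_sizes[controls]
  y <- sweep(mat$counts[, controls, drop = FALSE], 2, mean(es) / es, `*`)
  m <- rowMeans(y)
  v <- apply(y, 1, var)
  phi_i <- ifelse(m > 0, pmax(0, (v - m) / m^2), NA_real_)
  use <- !is.na(phi_i) & m >= min_mean
  phi <- if (any(use)) median(phi_i[use]) else floor
  list(phi = max(phi, floor), per_region_phi = phi_i)
}

#' Conditional negative-binomial exact test, one case versus n controls
#'
#' Counts are scaled to a common library size (the mean effective size) to
#' form integer pseudo-counts.  Conditional on the total of the case
#' pseudo-count and the summed control pseudo-count, the case count follows
#' the distribution of one NB(mu, phi) variate given the sum with n
#' independent NB(mu, phi) controls (per-sample mean `mu = total /
#' (n + 1)`); the two-sided p-value sums the probabilities of all splits no
#' more likely than the observed one.  With `phi = 0` this reduces to the
#' conditional binomial (Poisson) test.
#'
#' @param patient_count the case's region count.
#' @param control_counts vector of control region counts.
#' @param phi common NB dispersion (>= 0).
#' @param effective_sizes effective library sizes, case first then
#'   controls; `NULL` for equal sizes.
#' @return list with `p` and `log2fc` (case versus mean control, +0.5
#'   shrinkage on both).
#' @export
exact_nb_test <- function(patient_count, control_counts, phi,
                          effective_sizes = NULL) {
  if (phi < 0) stop("phi must be >= 0")
  n <- length(control_counts)
  stopifnot(n >= 1)
  if (is.null(effective_sizes)) effective_sizes <- rep(1, n + 1)
  stopifnot(length(effective_sizes) == n + 1)
  N <- mean(effective_sizes)
  yp <- round(patient_count * N / effective_sizes[1])
  yc <- round(control_counts * N / effective_sizes[-1])
  S <- sum(yc)
  total <- yp + S
  lfc <- log2((yp + 0.5) / (mean(yc) + 0.5))
  if (total == 0) return(list(p = 1, log2fc = 0))
  mu <- total / (n + 1)
  k <- 0:total
  if (phi > 0) {
    ll <- dnbinom(k, size = 1 / phi, mu = mu, log = TRUE) +
      dnbinom(total - k, size = n / phi, mu = n * mu, log = TRUE)
  } else {
    ll <- dpois(k, mu, log = TRUE) + dpois(total - k, n * mu, log = TRUE)
  }
  pr <- exp(ll - max(ll))
  pr <- pr / sum(pr)
  p_obs <- pr[yp + 1]
  p <- min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]))
  list(p = p, log2fc = lfc)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1 (delegates to [stats::p.adjust()]).
#'
#' @param p vector of raw p-values in (0, 1].
#' @return adjusted p-values.
#' @export
adjust_bh <- function(p) {
  stopifnot(length(p) >= 1, all(p > 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Per-case differential methylation against the control group
#'
#' Runs the exact NB test for every region, comparing each case sample
#' individually to the control group, with TMM-style normalization, a
#' common control-derived dispersion and per-case BH adjustment.
#'
#' @param mat a `region_count_matrix` (after [rpm_filter()]).
#' @param patients case sample ids tested one at a time.
#' @param controls control sample ids (>= 3).
#' @param alpha significance level on the adjusted p-value, inclusive
#'   (default 0.05).
#' @param dispersion optional fixed common dispersion; estimated from the
#'   controls when `NULL`.
#' @return object of class `mbd_diff`: a data.frame with one row per
#'   (region, case) holding `region_id`, `chrom`, `start`, `end`,
#'   `sample_id`, `log2fc`, `p_raw`, `p_adj` and `direction` (`"hypo"`,
#'   `"hyper"` or `"none"`); attributes `alpha`, `phi`, `factors`.
#' @export
mbd_diff <- function(mat, patients, controls, alpha = 0.05,
                     dispersion = NULL) {
  stopifnot(inherits(mat, "region_count_matrix"),
            all(patients %in% mat$samples), all(controls %in% mat$samples),
            length(intersect(patients, controls)) == 0)
  norm <- normalize_libraries(mat)
  es <- norm$effective_sizes
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(mat, controls, es)$phi
  }
  regions <- mat$regions
  res <- vector("list", length(patients))
  for (pi in seq_along(patients)) {
    p_id <- patients[pi]
    sizes <- c(es[p_id], es[controls])
    tst <- lapply(seq_len(nrow(regions)), function(i) {
      exact_nb_test(mat$counts[i, p_id], mat$counts[i, controls],
                    dispersion, sizes)
    })
    p_raw <- vapply(tst, `[[`, numeric(1), "p")
    log2fc <- vapply(tst, `[[`, numeric(1), "log2fc")
    p_adj <- adjust_bh(p_raw)
    direction <- rep("none", nrow(regions))
    sig <- p_adj <= alpha
    if (any(sig & log2fc == 0)) {
      stop("significant region with zero log2 fold change: inconsistent test")
    }
    direction[sig & log2fc < 0] <- "hypo"
    direction[sig & log2fc > 0] <- "hyper"
    res[[pi]] <- data.frame(
      region_id = regions$region_id, chrom = regions$chrom,
      start = regions$start, end = regions$end, sample_id = p_id,
      log2fc = log2fc, p_raw = p_raw, p_adj = p_adj,
      direction = direction, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("mbd_diff", "data.frame"), alpha = alpha,
            phi = dispersion, factors = norm$factors)
}

#' @export
print.mbd_diff <- function(x, ...) {
  alpha <- attr(x, "alpha")
  cat(sprintf(
    "Differential methylation: %d regions x %d case(s), phi = %.4g, alpha = %g\n",
    length(unique(x$region_id)), length(unique(x$sample_id)),
    attr(x, "phi"), alpha))
  tab <- table(x$sample_id, x$direction)
  print(tab)
  invisible(x)
}

#' @method summary mbd_diff
#' @export
summary.mbd_diff <- function(object, ...) {
  by_case <- split(object, object$sample_id)
  data.frame(
    sample_id = names(by_case),
    n_aberrant = vapply(by_case, function(d) sum(d$direction != "none"),
                        integer(1)),
    n_hypo = vapply(by_case, function(d) sum(d$direction == "hypo"),
                    integer(1)),
    n_hyper = vapply(by_case, function(d) sum(d$direction == "hyper"),
                     integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Extract aberrantly methylated regions per case
#'
#' A region is called when its BH-adjusted p-value is at or below `alpha`
#' (inclusive); direction follows the sign of the log2 fold change.
#'
#' @param results an `mbd_diff` object.
#' @param alpha significance level; defaults to the one stored in
#'   `results`.
#' @return named list (one element per case) of data.frames with
#'   `direction != "none"`.
#' @export
call_aberrant <- function(results, alpha = NULL) {
  stopifnot(inherits(results, "mbd_diff"))
  if (is.null(alpha)) alpha <- attr(results, "alpha")
  df <- as.data.frame(results)
  sig <- df$p_adj <= alpha
  if (any(sig & df$log2fc == 0)) {
    stop("significant region with zero log2 fold change: inconsistent test")
  }
  df$direction <- "none"
  df$direction[sig & df$log2fc < 0] <- "hypo"
  df$direction[sig & df$log2fc > 0] <- "hyper"
  lapply(split(df, df$sample_id), function(d) {
    d <- d[d$direction != "none", , drop = FALSE]
    rownames(d) <- NULL
    d
  })
}
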