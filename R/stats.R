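# 2x2 within-subject statistics: classical repeated-measures ANOVA with
# partial eta squared, the four follow-up paired contrasts with Bonferroni
# control, and noncentral-F power for the within-between interaction.

#' Build a complete 2x2 within-subject condition table
#'
#' @param subject Subject identifiers.
#' @param intervention Factor with levels `active`/`sham`.
#' @param block Factor with levels `pre`/`post`.
#' @param value Dependent-variable values.
#' @return data.frame of class `condition_table`, validated to contain all
#'   four cells for every subject and at least 3 subjects.
#' @export
condition_table <- function(subject, intervention, block, value) {
  df <- data.frame(subject = as.character(subject),
                   intervention = as.character(intervention),
                   block = as.character(block),
                   value = as.numeric(value), stringsAsFactors = FALSE)
  bad_iv <- setdiff(unique(df$intervention), c("active", "sham"))
  bad_bl <- setdiff(unique(df$block), c("pre", "post"))
  if (length(bad_iv) > 0) stop("unknown intervention level: ", bad_iv[1])
  if (length(bad_bl) > 0) stop("unknown block level: ", bad_bl[1])
  subs <- unique(df$subject)
  if (length(subs) < 3) stop("need at least 3 subjects")
  for (s in subs) for (iv in c("active", "sham")) for (bl in c("pre", "post")) {
    n <- sum(df$subject == s & df$intervention == iv & df$block == bl)
    if (n != 1)
      stop(sprintf("incomplete table: subject %s, cell %s/%s has %d values",
                   s, iv, bl, n))
  }
  structure(df, class = c("condition_table", "data.frame"))
}

table_cells <- function(table) {
  # matrix n_subjects x 4 in fixed cell order
  subs <- unique(table$subject)
  cells <- expand.grid(block = c("pre", "post"),
                       intervention = c("active", "sham"),
                       stringsAsFactors = FALSE)
  m <- matrix(0, nrow = length(subs), ncol = 4,
              dimnames = list(subs, paste(cells$intervention, cells$block,
                                          sep = "_")))
  for (i in seq_along(subs)) for (j in seq_len(4)) {
    sel <- table$subject == subs[i] &
      table$intervention == cells$intervention[j] &
      table$block == cells$block[j]
    m[i, j] <- table$value[sel]
  }
  m
}

#' Two-way repeated-measures ANOVA for the 2x2 within design
#'
#' Classical univariate decomposition: each effect is tested against its
#' effect-by-subject interaction, `F = MS_effect / MS_(effect x subject)`
#' with df (1, n-1); partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param table A [condition_table()].
#' @return An object of class `anova_result`: data.frame with one row per
#'   effect (`Block`, `Intervention`, `Interaction`) and columns `F`,
#'   `df1`, `df2`, `p`, `partial_eta_sq`.
#' @export
rm_anova_2x2 <- function(table) {
  if (!inherits(table, "condition_table"))
    table <- condition_table(table$subject, table$intervention, table$block,
                             table$value)
  m <- table_cells(table)  # columns: active_pre, active_post, sham_pre, sham_post
  n <- nrow(m)
  grand <- mean(m)
  subj_mean <- rowMeans(m)
  block_mean <- c(pre = mean(m[, c(1, 3)]), post = mean(m[, c(2, 4)]))
  iv_mean <- c(active = mean(m[, 1:2]), sham = mean(m[, 3:4]))

  ss_block <- 2 * n * sum((block_mean - grand)^2)
  ss_iv <- 2 * n * sum((iv_mean - grand)^2)
  cell_mean <- colMeans(m)
  blk <- rep(c("pre", "post"), 2)
  ivv <- rep(c("active", "sham"), each = 2)
  ss_cells <- n * sum((cell_mean - grand)^2)
  ss_int <- ss_cells - ss_block - ss_iv

  # error strata: effect x subject interactions
  subj_block <- cbind(pre = rowMeans(m[, c(1, 3)]),
                      post = rowMeans(m[, c(2, 4)]))
  ss_bs <- 2 * sum((subj_block - outer(subj_mean, c(1, 1)) -
                      matrix(block_mean, n, 2, byrow = TRUE) + grand)^2)
  subj_iv <- cbind(active = rowMeans(m[, 1:2]), sham = rowMeans(m[, 3:4]))
  ss_is <- 2 * sum((subj_iv - outer(subj_mean, c(1, 1)) -
                      matrix(iv_mean, n, 2, byrow = TRUE) + grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_subj <- 4 * sum((subj_mean - grand)^2)
  # subtraction can leave tiny negative residues in degenerate tables
  ss_bis <- max(0, ss_total - ss_subj - ss_block - ss_iv - ss_int -
                  ss_bs - ss_is)
  ss_int <- max(0, ss_int)

  df2 <- n - 1
  eff <- function(name, ss_eff, ss_err) {
    ms_eff <- ss_eff / 1
    ms_err <- ss_err / df2
    f <- if (ms_err == 0) 0 else ms_eff / ms_err
    data.frame(effect = name, F = f, df1 = 1, df2 = df2,
               p = stats::pf(f, 1, df2, lower.tail = FALSE),
               partial_eta_sq = if (ss_eff + ss_err == 0) 0 else
                 ss_eff / (ss_eff + ss_err),
               stringsAsFactors = FALSE)
  }
  res <- rbind(eff("Block", ss_block, ss_bs),
               eff("Intervention", ss_iv, ss_is),
               eff("Interaction", ss_int, ss_bis))
  structure(res, class = c("anova_result", "data.frame"))
}

#' Follow-up paired t-tests for the 2x2 design
#'
#' The four canonical contrasts: sham pre vs sham post, active pre vs
#' active post, sham pre vs active pre, sham post vs active post. Two-sided
#' paired t with df = n-1; significance is flagged against the Bonferroni
#' threshold for the four-test family.
#'
#' @param table A [condition_table()].
#' @param family_alpha Family-wise alpha (default 0.05).
#' @return data.frame with columns `contrast`, `t`, `df`, `p`,
#'   `significant`.
#' @export
posthoc_paired_tests <- function(table, family_alpha = 0.05) {
  if (!inherits(table, "condition_table"))
    table <- condition_table(table$subject, table$intervention, table$block,
                             table$value)
  m <- table_cells(table)
  contrasts <- list(
    "sham pre vs sham post" = m[, "sham_pre"] - m[, "sham_post"],
    "active pre vs active post" = m[, "active_pre"] - m[, "active_post"],
    "sham pre vs active pre" = m[, "sham_pre"] - m[, "active_pre"],
    "sham post vs active post" = m[, "sham_post"] - m[, "active_post"]
  )
  thr <- bonferroni_threshold(family_alpha, length(contrasts))
  rows <- lapply(names(contrasts), function(nm) {
    d <- contrasts[[nm]]
    n <- length(d)
    sdv <- stats::sd(d)
    if (sdv == 0 && mean(d) != 0)
      stop("zero variance of paired differences in contrast: ", nm)
    t <- if (sdv == 0) 0 else mean(d) / (sdv / sqrt(n))
    p <- 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE)
    data.frame(contrast = nm, t = t, df = n - 1, p = p,
               significant = p < thr, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bonferroni-corrected per-test alpha
#'
#' @param family_alpha Family-wise error rate (default 0.05).
#' @param k Number of tests in the family (default 4).
#' @return `family_alpha / k`.
#' @export
bonferroni_threshold <- function(family_alpha = 0.05, k = 4) {
  stopifnot(k >= 1, family_alpha > 0, family_alpha < 1)
  family_alpha / k
}

#' Power specification for the within-between interaction
#'
#' Conventions of the classical repeated-measures power template: Cohen's
#' `f^2 = eta_p^2 / (1 - eta_p^2)`, noncentrality
#' `lambda = f^2 * N * m * epsilon / (1 - rho)`, numerator df
#' `(g-1)(m-1)`, denominator df `(N-g)(m-1)*epsilon`.
#'
#' @param eta_p_sq Partial eta squared of the interaction, in [0, 1).
#' @param N Total number of subjects.
#' @param g Number of groups (default 2).
#' @param m Number of repeated measurements (default 2).
#' @param rho Repeated-measures correlation (default 0.5).
#' @param epsilon Nonsphericity correction (default 1).
#' @param alpha Test level (default 0.05).
#' @return An object of class `power_spec`.
#' @export
power_spec <- function(eta_p_sq, N, g = 2, m = 2, rho = 0.5, epsilon = 1,
                       alpha = 0.05) {
  stopifnot(eta_p_sq >= 0, eta_p_sq < 1, rho >= 0, rho < 1,
            alpha > 0, alpha < 1, g >= 2, m >= 2, epsilon > 0)
  if (!is.null(N) && N <= g) stop("N must exceed the number of groups")
  structure(list(eta_p_sq = eta_p_sq, N = N, g = g, m = m, rho = rho,
                 epsilon = epsilon, alpha = alpha), class = "power_spec")
}

#' Power of the within-between interaction test
#'
#' Computes the probability that the noncentral F statistic of the
#' group-by-time interaction exceeds its critical value.
#'
#' @param spec A [power_spec()].
#' @return Power in [0, 1].
#' @export
interaction_power <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  f2 <- spec$eta_p_sq / (1 - spec$eta_p_sq)
  lambda <- f2 * spec$N * spec$m * spec$epsilon / (1 - spec$rho)
  df1 <- (spec$g - 1) * (spec$m - 1)
  df2 <- (spec$N - spec$g) * (spec$m - 1) * spec$epsilon
  fcrit <- stats::qf(1 - spec$alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Smallest sample size reaching a target interaction power
#'
#' Integer search upward from `N = g + 1`.
#'
#' @param spec A [power_spec()]; its `N` is ignored.
#' @param target_power Desired power in (alpha, 1).
#' @param n_max Search cap (default 10000).
#' @return The smallest `N` with power >= `target_power`.
#' @export
required_sample_size <- function(spec, target_power = 0.8, n_max = 10000) {
  stopifnot(inherits(spec, "power_spec"),
            target_power > spec$alpha, target_power < 1)
  for (N in (spec$g + 1):n_max) {
    s <- spec; s$N <- N
    if (interaction_power(s) >= target_power) return(N)
  }
  stop("no N up to ", n_max, " reaches the target power")
}
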