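# Clinical statistics: rest/drop/diff pH, saliva normalisation, Welch and
# permutation comparisons, and a seeded synthetic cohort generator.

#' Difference between rest and drop pH
#'
#' `rest - drop`: positive when the sugar rinse acidified the biofilm.
#' Missing operands give a missing result (no imputation).
#'
#' @param rest,drop aggregated surface pH before and one minute after the
#'   sucrose rinse (vectors allowed).
#' @return `rest - drop`.
#' @export
diff_ph <- function(rest, drop) {
  stopifnot(length(rest) == length(drop))
  rest - drop
}

#' Normalise a biofilm pH by the subject's saliva pH
#'
#' Saliva pH is near-neutral across subjects and serves as a per-subject
#' baseline; the normalised metric is the unitless quotient
#' `biofilm pH / saliva pH`. Subtraction (`biofilm - saliva`) is available
#' as an alternative convention.
#'
#' @param ph biofilm pH value(s).
#' @param saliva_ph subject's saliva pH (> 0 for the quotient).
#' @param method `"divide"` (default) or `"subtract"`.
#' @return Normalised value(s); missing saliva gives missing output.
#' @export
normalize_by_saliva <- function(ph, saliva_ph, method = c("divide", "subtract")) {
  method <- match.arg(method)
  if (method == "divide") {
    if (any(saliva_ph <= 0, na.rm = TRUE)) stop("saliva_ph must be positive")
    ph / saliva_ph
  } else {
    ph - saliva_ph
  }
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test for groups of unequal size, as used to compare
#' pH metrics between cleaning groups. Thin wrapper over [stats::t.test()]
#' returning the statistic, Welch-Satterthwaite degrees of freedom and the
#' two-sided p-value.
#'
#' @param a,b numeric vectors, each with n >= 2.
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
welch_t_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    # t.test errors on doubly-constant data; identical groups are a null result
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    stop("both groups have zero variance but different means")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Two-sample permutation test on the difference of means
#'
#' Two-sided test with statistic `|mean(a) - mean(b)|`. When the number of
#' distinct label assignments `choose(na + nb, na)` is at most
#' `exhaustive_limit`, all assignments are enumerated and the p-value is the
#' exact proportion of assignments whose statistic reaches the observed one
#' (the observed assignment is among them). Otherwise `n_perm` random
#' shuffles are drawn and the add-one estimate
#' `(#{perm >= obs} + 1) / (n_perm + 1)` is returned.
#'
#' @param a,b numeric vectors, each nonempty.
#' @param n_perm number of random shuffles in sampled mode.
#' @param seed optional integer seed for sampled mode.
#' @param exhaustive_limit enumeration cutoff on `choose(na + nb, na)`.
#' @return List with `p`, `observed`, `mode` (`"exhaustive"` or
#'   `"sampled"`), and `n_perm` (number of assignments examined).
#' @examples
#' permutation_test(c(1, 2), c(10, 11))$p  # exactly 1/3
#' @export
permutation_test <- function(a, b, n_perm = 10000, seed = NULL,
                             exhaustive_limit = 20000) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 1, nb >= 1, n_perm >= 1)
  pool <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  tol <- 1e-9 * max(obs, 1)  # count floating-point ties as >=
  total <- sum(pool)
  n <- na + nb
  stat_from_idx <- function(idx) {
    sa <- sum(pool[idx])
    abs(sa / na - (total - sa) / nb)
  }
  if (choose(n, na) <= exhaustive_limit) {
    splits <- utils::combn(n, na)
    stats_all <- apply(splits, 2, stat_from_idx)
    list(p = mean(stats_all >= obs - tol), observed = obs,
         mode = "exhaustive", n_perm = ncol(splits))
  } else {
    if (!is.null(seed)) set.seed(seed)
    stats_all <- vapply(seq_len(n_perm), function(i) {
      stat_from_idx(sample.int(n, na))
    }, numeric(1))
    list(p = (sum(stats_all >= obs - tol) + 1) / (n_perm + 1),
         observed = obs, mode = "sampled", n_perm = n_perm)
  }
}

#' Default parameters of the synthetic clinical cohort
#'
#' The defaults emulate the study conditions: a Pre-Cleaning group (no
#' professional cleaning for over three months; 7 subjects, 40 measured
#' surfaces) and a Post-Cleaning group (cleaned within three months; 18
#' subjects, 45 surfaces), rest pH measured before and drop pH one minute
#' after a sucrose rinse, three replicates per surface with replicate noise
#' at the device's pooled SD of 0.23 pH, and group diff-pH means of 0.84
#' (Pre) and 0.48 (Post). Group rest means (6.65 / 6.80) are set so that the
#' surface-weighted rank-0 rest mean is 6.73. Carious (rank 1) surfaces are
#' shifted slightly upward in rest pH, matching the reported caries-surface
#' means.
#'
#' @param ... named overrides of any default component.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(...) {
  p <- list(
    n_subjects = c(pre = 7, post = 18),
    n_surfaces = c(pre = 40, post = 45),
    rank1_fraction = 0.2,
    rest_mean = c(pre = 6.65, post = 6.80),
    diff_mean = c(pre = 0.84, post = 0.48),
    rank1_rest_shift = 0.08,
    rank1_diff_shift = 0.01,
    surface_sd_rest = 0.35,
    surface_sd_diff = 0.30,
    replicate_sd = 0.23,
    n_replicates = 3,
    saliva_mean = 7.0,
    saliva_sd = 0.2,
    ph_range = c(4, 7.5),
    n_rest_measured = NULL,   # NULL: rest measured at every surface
    n_drop_measured = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown cohort parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  structure(p, class = "cohort_params")
}

#' Generate a synthetic clinical cohort
#'
#' Draws surface-level true rest pH and diff pH from group- and rank-specific
#' normals (drop = rest - diff), adds replicate noise at the pooled-SD level,
#' clips replicate readings to the accepted pH range, and aggregates
#' replicates to surface values. Saliva pH is drawn per subject from a
#' truncated normal. If `n_rest_measured` / `n_drop_measured` are set, only
#' the first / last so many surfaces carry that phase, emulating spots lost
#' to quality gating.
#'
#' @param params a [cohort_params()] list.
#' @param seed optional integer seed; identical seeds give identical tables.
#' @return A list of class `oph_cohort` with data frames `surfaces`
#'   (subject_id, group, surface_id, rank, rest_ph, drop_ph), `subjects`
#'   (subject_id, group, saliva_ph) and `readings` (one row per replicate:
#'   subject_id, group, surface_id, rank, phase, replicate, ph).
#' @examples
#' coh <- synth_cohort(seed = 1)
#' head(coh$surfaces)
#' @export
synth_cohort <- function(params = cohort_params(), seed = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  if (!is.null(seed)) set.seed(seed)
  groups <- names(params$n_surfaces)
  lo <- params$ph_range[1]; hi <- params$ph_range[2]

  subjects <- do.call(rbind, lapply(groups, function(g) {
    n <- params$n_subjects[[g]]
    data.frame(subject_id = sprintf("%s%02d", g, seq_len(n)),
               group = g,
               saliva_ph = pmin(pmax(stats::rnorm(n, params$saliva_mean,
                                                  params$saliva_sd),
                                     5.5), 8.5))
  }))

  surf_list <- list(); read_list <- list()
  for (g in groups) {
    ns <- params$n_surfaces[[g]]
    subj <- subjects$subject_id[subjects$group == g]
    sid <- sprintf("%s_s%03d", g, seq_len(ns))
    owner <- rep(subj, length.out = ns)
    rank <- stats::rbinom(ns, 1, params$rank1_fraction)
    true_rest <- stats::rnorm(ns, params$rest_mean[[g]] +
                                params$rank1_rest_shift * rank,
                              params$surface_sd_rest)
    true_diff <- stats::rnorm(ns, params$diff_mean[[g]] +
                                params$rank1_diff_shift * rank,
                              params$surface_sd_diff)
    true_rest <- pmin(pmax(true_rest, lo), hi)
    true_drop <- pmin(pmax(true_rest - true_diff, lo), hi)
    has_rest <- rep(TRUE, ns); has_drop <- rep(TRUE, ns)
    if (!is.null(params$n_rest_measured)) {
      nr <- round(params$n_rest_measured * ns / sum(params$n_surfaces))
      has_rest <- seq_len(ns) <= nr
    }
    has_drop_n <- params$n_drop_measured
    if (!is.null(has_drop_n)) {
      nd <- round(has_drop_n * ns / sum(params$n_surfaces))
      has_drop <- seq_len(ns) > ns - nd
    }
    reps <- params$n_replicates
    for (phase in c("rest", "drop")) {
      truth <- if (phase == "rest") true_rest else true_drop
      measured <- if (phase == "rest") has_rest else has_drop
      idx <- which(measured)
      if (!length(idx)) next
      ph <- rep(truth[idx], each = reps) +
        stats::rnorm(length(idx) * reps, 0, params$replicate_sd)
      read_list[[paste(g, phase)]] <- data.frame(
        subject_id = rep(owner[idx], each = reps),
        group = g,
        surface_id = rep(sid[idx], each = reps),
        rank = rep(rank[idx], each = reps),
        phase = phase,
        replicate = rep(seq_len(reps), times = length(idx)),
        ph = pmin(pmax(ph, lo), hi))
    }
    surf_list[[g]] <- data.frame(subject_id = owner, group = g,
                                 surface_id = sid, rank = rank,
                                 has_rest = has_rest, has_drop = has_drop)
  }
  readings <- do.call(rbind, read_list)
  rownames(readings) <- NULL
  surfaces <- do.call(rbind, surf_list)

  agg <- function(phase) {
    r <- readings[readings$phase == phase, ]
    if (!nrow(r)) return(numeric(0))
    tapply(r$ph, r$surface_id, mean)
  }
  rest_agg <- agg("rest"); drop_agg <- agg("drop")
  surfaces$rest_ph <- ifelse(surfaces$has_rest,
                             rest_agg[surfaces$surface_id], NA_real_)
  surfaces$drop_ph <- ifelse(surfaces$has_drop,
                             drop_agg[surfaces$surface_id], NA_real_)
  surfaces$has_rest <- surfaces$has_drop <- NULL
  rownames(surfaces) <- NULL
  structure(list(surfaces = surfaces, subjects = subjects,
                 readings = readings, params = params),
            class = "oph_cohort")
}

#' Count surface-level measurements and replicate readings in a cohort
#'
#' @param cohort an `oph_cohort` (see [synth_cohort()]).
#' @return List with `n_rest` and `n_drop` (surfaces measured per phase),
#'   `measurements` (their sum: surface-level rest + drop values) and
#'   `readings` (individual replicate readings).
#' @export
count_readings <- function(cohort) {
  s <- cohort$surfaces
  list(n_rest = sum(!is.na(s$rest_ph)),
       n_drop = sum(!is.na(s$drop_ph)),
       measurements = sum(!is.na(s$rest_ph)) + sum(!is.na(s$drop_ph)),
       readings = nrow(cohort$readings))
}

# Shapiro-Wilk normality gate; NA when the sample size is outside the
# test's 3..5000 support.
.shapiro_p <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(x) > 5000) return(NA_real_)
  if (stats::var(x) == 0) return(0)
  stats::shapiro.test(x)$p.value
}

#' Run the full grid of clinical group comparisons
#'
#' Reproduces the study's comparison structure on a cohort: for each pH
#' metric (rest, drop, diff), raw and saliva-normalised, compare (a) the two
#' cleaning groups over all surfaces, (b) the cleaning groups within each
#' caries rank, and (c) rank 0 vs rank 1 within each group. Every cell gets
#' a permutation test; Welch's t-test is reported only when both samples
#' pass a Shapiro-Wilk normality check at the same alpha (otherwise `NA`,
#' as for non-normal rank-1 data in the study). Cells with fewer than two
#' values per side are skipped with a warning.
#'
#' @param cohort an `oph_cohort`, or a list with `surfaces` and `subjects`
#'   data frames in the [synth_cohort()] layout.
#' @param alpha significance level (default 0.05).
#' @param n_perm permutations per sampled test.
#' @param seed integer seed governing all permutation draws.
#' @param metrics,normalized,comparisons subsets of the comparison grid to
#'   run; defaults run everything.
#' @param normalize_method passed to [normalize_by_saliva()].
#' @return A data frame of class `oph_comparisons`, one row per comparison
#'   cell, deterministically ordered, with group means, Shapiro p-values,
#'   Welch statistic/df/p (or `NA`), permutation p and a significance flag
#'   based on the permutation p-value.
#' @export
analyze_cohort <- function(cohort, alpha = 0.05, n_perm = 10000, seed = 1,
                           metrics = c("rest", "drop", "diff"),
                           normalized = c(FALSE, TRUE),
                           comparisons = c("group", "rank_between",
                                           "rank_within"),
                           normalize_method = "divide") {
  surfaces <- cohort$surfaces
  subjects <- cohort$subjects
  metrics <- match.arg(metrics, several.ok = TRUE)
  comparisons <- match.arg(comparisons, several.ok = TRUE)

  d <- merge(surfaces, subjects[, c("subject_id", "saliva_ph")],
             by = "subject_id", sort = FALSE)
  d$diff <- diff_ph(d$rest_ph, d$drop_ph)
  d$rest <- d$rest_ph; d$drop <- d$drop_ph
  for (m in c("rest", "drop", "diff"))
    d[[paste0(m, "_norm")]] <- normalize_by_saliva(d[[m]], d$saliva_ph,
                                                   normalize_method)
  groups <- sort(unique(d$group))

  cells <- list()
  add <- function(metric, norm, comparison, stratum, la, lb, a, b) {
    cells[[length(cells) + 1]] <<- list(metric = metric, normalized = norm,
                                        comparison = comparison,
                                        stratum = stratum,
                                        group_a = la, group_b = lb,
                                        a = a, b = b)
  }
  for (m in metrics) for (norm in normalized) {
    col <- if (norm) paste0(m, "_norm") else m
    val <- function(rows) { v <- d[[col]][rows]; v[is.finite(v)] }
    if ("group" %in% comparisons && length(groups) >= 2)
      add(m, norm, "group", "all", groups[1], groups[2],
          val(d$group == groups[1]), val(d$group == groups[2]))
    if ("rank_between" %in% comparisons && length(groups) >= 2)
      for (rk in c(0, 1))
        add(m, norm, "rank_between", paste0("rank", rk),
            groups[1], groups[2],
            val(d$group == groups[1] & d$rank == rk),
            val(d$group == groups[2] & d$rank == rk))
    if ("rank_within" %in% comparisons)
      for (g in groups)
        add(m, norm, "rank_within", g, "rank0", "rank1",
            val(d$group == g & d$rank == 0),
            val(d$group == g & d$rank == 1))
  }

  rows <- lapply(seq_along(cells), function(i) {
    ce <- cells[[i]]
    base <- data.frame(metric = ce$metric, normalized = ce$normalized,
                       comparison = ce$comparison, stratum = ce$stratum,
                       group_a = ce$group_a, group_b = ce$group_b,
                       n_a = length(ce$a), n_b = length(ce$b),
                       mean_a = NA_real_, mean_b = NA_real_,
                       shapiro_p_a = NA_real_, shapiro_p_b = NA_real_,
                       normal = NA, welch_t = NA_real_, welch_df = NA_real_,
                       welch_p = NA_real_, perm_p = NA_real_, alpha = alpha,
                       significant = NA)
    if (length(ce$a) < 2 || length(ce$b) < 2) {
      warning(sprintf("skipping %s/%s/%s: fewer than 2 values per group",
                      ce$metric, ce$comparison, ce$stratum), call. = FALSE)
      return(base)
    }
    base$mean_a <- mean(ce$a); base$mean_b <- mean(ce$b)
    base$shapiro_p_a <- .shapiro_p(ce$a)
    base$shapiro_p_b <- .shapiro_p(ce$b)
    base$normal <- isTRUE(base$shapiro_p_a > alpha &&
                          base$shapiro_p_b > alpha)
    if (base$normal) {
      w <- welch_t_test(ce$a, ce$b)
      base$welch_t <- w$t; base$welch_df <- w$df; base$welch_p <- w$p
    }
    pt <- permutation_test(ce$a, ce$b, n_perm = n_perm,
                           seed = seed + i)
    base$perm_p <- pt$p
    base$significant <- pt$p < alpha
    base
  })
  out <- do.call(rbind, rows)
  class(out) <- c("oph_comparisons", class(out))
  out
}
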