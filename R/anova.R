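#' Two-way (or one-way) repeated-measures ANOVA
#'
#' Classical univariate within-subject decomposition on participant-level cell
#' means: each effect is tested against its participant-by-effect interaction
#' error stratum (fit via `stats::aov` with an `Error(id/(A*B))` term). For
#' every effect with three or more levels, Mauchly's sphericity test and the
#' Greenhouse-Geisser epsilon are computed from the covariance of orthonormal
#' contrast scores, and the Greenhouse-Geisser-corrected p-value is reported.
#' The correction is *applied* (used as `p_reported`) only when Mauchly's test
#' is significant at 0.05; both p-values are always returned.
#'
#' Trial-level data never enter the model: if `data` carries several rows per
#' participant x cell they are averaged first, matching the convention of
#' analysing mean baseline-corrected judgment errors.
#'
#' @param data Long-format data frame.
#' @param dv Name of the response column (character).
#' @param within Character vector of one or two within-subject factor columns.
#' @param id Name of the participant identifier column.
#' @return An `anova_result`: a tibble with one row per effect (`effect`,
#'   `df_effect`, `df_error`, `F`, `p`, `partial_eta_sq`, `mauchly_W`,
#'   `mauchly_p`, `gg_epsilon`, `p_gg`, `correction_applied`, `p_reported`).
#' @examples
#' d <- expand.grid(id = factor(1:8), speed = factor(c(1280, 2560, 5120)))
#' set.seed(1); d$y <- rnorm(nrow(d))
#' rm_anova(d, dv = "y", within = "speed", id = "id")
#' @export
rm_anova <- function(data, dv, within, id = "participant_id") {
  stopifnot(length(within) %in% 1:2, dv %in% names(data), id %in% names(data),
            all(within %in% names(data)))
  d <- tibble::as_tibble(data[c(id, within, dv)])
  names(d) <- c(".id", paste0(".f", seq_along(within)), ".y")
  for (v in c(".id", paste0(".f", seq_along(within)))) d[[v]] <- factor(d[[v]])
  d <- dplyr::summarise(
    dplyr::group_by(d, dplyr::across(dplyr::all_of(c(".id", paste0(".f", seq_along(within)))))),
    .y = mean(.data$.y), .groups = "drop"
  )

  lev <- lapply(paste0(".f", seq_along(within)), function(v) levels(d[[v]]))
  n_cells <- prod(lengths(lev))
  counts <- table(d$.id)
  if (any(counts != n_cells) || nrow(d) != nlevels(d$.id) * n_cells) {
    full <- do.call(expand.grid, c(list(.id = levels(d$.id)), stats::setNames(lev, paste0(".f", seq_along(within)))))
    have <- do.call(paste, c(d[c(".id", paste0(".f", seq_along(within)))], sep = "\r"))
    want <- do.call(paste, c(lapply(full, as.character), sep = "\r"))
    missing <- full[!(want %in% have), , drop = FALSE]
    stop("incomplete within-subject design; missing cell(s): ",
         paste(utils::head(do.call(paste, c(lapply(missing, as.character), sep = "/")), 8L),
               collapse = ", "), call. = FALSE)
  }

  fml <- if (length(within) == 1L) {
    .y ~ .f1 + Error(.id / .f1)
  } else {
    .y ~ .f1 * .f2 + Error(.id / (.f1 * .f2))
  }
  fit <- stats::aov(fml, data = d)
  smry <- summary(fit)

  effects <- if (length(within) == 1L) ".f1" else c(".f1", ".f2", ".f1:.f2")
  labels <- if (length(within) == 1L) within else
    c(within[1L], within[2L], paste(within, collapse = ":"))

  ss_scale <- sum(vapply(smry, function(s) sum(s[[1L]]$`Sum Sq`), numeric(1L)))
  extract <- function(term) {
    for (stratum in smry) {
      tab <- stratum[[1L]]
      rn <- trimws(rownames(tab))
      hit <- which(rn == term)
      if (length(hit)) {
        res <- which(rn == "Residuals")
        out <- list(df1 = tab$Df[hit], df2 = tab$Df[res],
                    F = tab$`F value`[hit], p = tab$`Pr(>F)`[hit])
        # degenerate stratum: no between-condition variance at all (effect and
        # error SS both vanish) -- the effect is absent, the test undefined
        tol <- 1e-10 * max(ss_scale, 1)
        if (tab$`Sum Sq`[hit] < tol && tab$`Sum Sq`[res] < tol) {
          out$F <- 0
          out$p <- NA_real_
        }
        return(out)
      }
    }
    stop("internal error: term ", term, " not found in aov summary.")
  }

  # participant x cell matrix, cells ordered first factor slowest
  dd <- dplyr::arrange(d, !!!rlang::syms(paste0(".f", seq_along(within))), .data$.id)
  Y <- matrix(dd$.y, nrow = nlevels(d$.id), ncol = n_cells)

  rows <- purrr::map2(effects, labels, function(term, label) {
    e <- extract(term)
    sph <- sphericity_stats(Y, term, lev)
    F_ <- max(e$F, 0)
    p_gg <- if (is.na(sph$eps)) e$p else
      stats::pf(F_, e$df1 * sph$eps, e$df2 * sph$eps, lower.tail = FALSE)
    applied <- !is.na(sph$mauchly_p) && sph$mauchly_p < 0.05
    tibble::tibble(
      effect = label, df_effect = e$df1, df_error = e$df2, F = e$F, p = e$p,
      partial_eta_sq = partial_eta_squared(F_, e$df1, e$df2),
      mauchly_W = sph$W, mauchly_p = sph$mauchly_p, gg_epsilon = sph$eps,
      p_gg = p_gg, correction_applied = applied,
      p_reported = if (applied) p_gg else e$p
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("anova_result", class(out))
  out
}

# Orthonormal contrast matrix (rows = contrasts) for one effect over the cell
# grid; cells are ordered with the first factor varying slowest.
effect_contrasts <- function(term, lev) {
  involved <- strsplit(term, ":", fixed = TRUE)[[1L]]
  parts <- lapply(seq_along(lev), function(i) {
    k <- length(lev[[i]])
    if (paste0(".f", i) %in% involved) t(stats::contr.poly(k))
    else matrix(1 / sqrt(k), nrow = 1L, ncol = k)
  })
  Reduce(kronecker, parts)
}

# Mauchly's W (with chi-square p) and Greenhouse-Geisser epsilon for one
# effect, from the covariance of orthonormal contrast scores.
sphericity_stats <- function(Y, term, lev) {
  C <- effect_contrasts(term, lev)
  k <- nrow(C)
  if (k < 2L) return(list(W = NA_real_, mauchly_p = NA_real_, eps = NA_real_))
  scores <- Y %*% t(C)
  S <- stats::cov(scores)
  n <- nrow(Y)
  tr <- sum(diag(S))
  if (tr < 1e-300) {  # zero contrast variance: diagnostics undefined
    return(list(W = NA_real_, mauchly_p = NA_real_, eps = NA_real_))
  }
  eps <- tr^2 / (k * sum(S * S))
  eps <- min(1, max(1 / k, eps))
  W <- det(S) / (tr / k)^k
  if (!is.finite(W) || W <= 0) {
    return(list(W = W, mauchly_p = 0, eps = eps))
  }
  nd <- n - 1
  f <- 1 - (2 * k^2 + k + 2) / (6 * k * nd)
  chi2 <- -f * nd * log(W)
  df <- k * (k + 1) / 2 - 1
  list(W = W, mauchly_p = stats::pchisq(chi2, df, lower.tail = FALSE), eps = eps)
}

#' Partial eta-squared from an F statistic
#'
#' `F * df_effect / (F * df_effect + df_error)`, the proportion of
#' effect-plus-error variance attributable to the effect.
#'
#' @param f F statistic (>= 0).
#' @param df_effect,df_error Degrees of freedom (> 0).
#' @return Effect size in `[0, 1]`.
#' @examples
#' partial_eta_squared(10.18, 1, 39)  # 0.207
#' @export
partial_eta_squared <- function(f, df_effect, df_error) {
  stopifnot(all(f >= 0), all(df_effect > 0), all(df_error > 0))
  f * df_effect / (f * df_effect + df_error)
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Repeated-measures ANOVA (participant-level cell means)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Bonferroni-corrected pairwise paired comparisons
#'
#' Paired t-tests on participant-level means between every pair of levels of a
#' within-subject factor; each p-value is multiplied by the number of pairs
#' and capped at 1. Cohen's d is reported in two flavours: `d_z` (mean
#' difference over the SD of the paired differences) and `d_pooled` (mean
#' difference over the root mean square of the two level SDs); published
#' clock-timing reports are not consistent about which is used, so both are
#' given and neither is privileged.
#'
#' @param data Long-format data frame (one or more rows per participant x
#'   level; rows are averaged per participant x level first).
#' @param dv,factor,id Column names (character) for the response, the factor
#'   and the participant identifier.
#' @return Tibble with one row per level pair: `contrast`, `mean_diff`, `t`,
#'   `df`, `p`, `p_bonferroni`, `d_z`, `d_pooled`, `n_comparisons`.
#' @export
bonferroni_pairwise <- function(data, dv, factor, id = "participant_id") {
  d <- tibble::as_tibble(data[c(id, factor, dv)])
  names(d) <- c(".id", ".f", ".y")
  d$.f <- base::factor(d$.f)
  d <- dplyr::summarise(dplyr::group_by(d, .data$.id, .data$.f),
                        .y = mean(.data$.y), .groups = "drop")
  wide <- tidyr::pivot_wider(d, names_from = ".f", values_from = ".y")
  levs <- levels(d$.f)
  if (length(levs) < 2L) stop("`factor` needs at least 2 levels.", call. = FALSE)
  if (anyNA(wide[levs])) stop("incomplete participant x level matrix.", call. = FALSE)
  pairs <- utils::combn(levs, 2L, simplify = FALSE)
  m <- length(pairs)
  purrr::map_dfr(pairs, function(pr) {
    x <- wide[[pr[1L]]]; y <- wide[[pr[2L]]]
    diffs <- x - y
    n <- length(diffs)
    if (stats::sd(diffs) == 0) {
      # degenerate pair: identical profiles (p = 1) or a constant offset (p = 0)
      tstat <- if (mean(diffs) == 0) 0 else sign(mean(diffs)) * Inf
      pval <- if (mean(diffs) == 0) 1 else 0
    } else {
      tt <- stats::t.test(x, y, paired = TRUE)
      tstat <- unname(tt$statistic)
      pval <- tt$p.value
    }
    tibble::tibble(
      contrast = paste(pr, collapse = " vs "),
      mean_diff = mean(diffs),
      t = tstat, df = n - 1,
      p = pval,
      p_bonferroni = min(1, pval * m),
      d_z = mean(diffs) / stats::sd(diffs),
      d_pooled = mean(diffs) / sqrt((stats::var(x) + stats::var(y)) / 2),
      n_comparisons = m
    )
  })
}

#' Cousineau within-subject confidence intervals
#'
#' Removes between-participant variance by normalising each observation:
#' subtract the participant's own mean across conditions and add back the
#' grand mean. The CI half-width per condition is
#' `t(n-1, level) * SD(normalised) / sqrt(n)`. The Morey correction factor
#' `sqrt(J/(J-1))` (J = number of conditions), which compensates for the
#' variance shrinkage the normalisation induces, is available but off by
#' default, matching the original Cousineau procedure.
#'
#' @param data Long-format data frame, one row per participant x condition
#'   (multiple rows are averaged).
#' @param dv,id Column names for the response and the participant identifier.
#' @param conditions Character vector of one or more condition columns; their
#'   combination defines the J cells.
#' @param level Confidence level (default 0.95).
#' @param morey Apply the Morey correction factor (default `FALSE`).
#' @return Tibble with one row per condition: the condition columns, `mean`,
#'   `ci_half_width`, `n`, `level`.
#' @export
cousineau_ci <- function(data, dv, conditions, id = "participant_id",
                         level = 0.95, morey = FALSE) {
  d <- tibble::as_tibble(data[c(id, conditions, dv)])
  names(d)[names(d) == dv] <- ".y"
  names(d)[names(d) == id] <- ".id"
  d <- dplyr::summarise(
    dplyr::group_by(d, dplyr::across(dplyr::all_of(c(".id", conditions)))),
    .y = mean(.data$.y), .groups = "drop"
  )
  cell_counts <- dplyr::count(d, dplyr::across(dplyr::all_of(".id")))
  J <- dplyr::n_distinct(d[conditions])
  if (any(cell_counts$n != J)) {
    stop("incomplete participant x condition matrix.", call. = FALSE)
  }
  grand <- mean(d$.y)
  d <- dplyr::mutate(dplyr::group_by(d, .data$.id),
                     .norm = .data$.y - mean(.data$.y) + grand)
  d <- dplyr::ungroup(d)
  corr <- if (morey) sqrt(J / (J - 1)) else 1
  out <- dplyr::summarise(
    dplyr::group_by(d, dplyr::across(dplyr::all_of(conditions))),
    mean = mean(.data$.y),
    ci_half_width = corr * stats::qt(1 - (1 - level) / 2, dplyr::n() - 1) *
      stats::sd(.data$.norm) / sqrt(dplyr::n()),
    n = dplyr::n(),
    .groups = "drop"
  )
  out$level <- level
  out
}
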