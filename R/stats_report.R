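# Stage-wise group comparisons: pairwise two-sided Mann-Whitney-Wilcoxon
# with Bonferroni correction (ROIs as independent sample points), the
# Kruskal-Wallis omnibus test, significance-star annotation, and report
# generation.

#' Significance stars for a p-value
#'
#' ns: p > 0.05; *: p <= 0.05; **: p <= 0.01; ***: p <= 0.001;
#' ****: p <= 0.0001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
star_code <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p <= 1e-4 ~ "****",
    p <= 1e-3 ~ "***",
    p <= 1e-2 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Pairwise Mann-Whitney-Wilcoxon tests with Bonferroni correction
#'
#' Two-sided rank-sum test for each requested stage pair. The exact
#' enumeration p-value is used for small tie-free samples (combined n <= 12);
#' otherwise the normal approximation with tie correction and continuity
#' correction. The Bonferroni family is the set of tested pairs (adjusted
#' p = min(1, p * number of pairs)); stars are computed from the adjusted p.
#'
#' @param values_by_stage Named list: stage -> numeric vector (one value per
#'   ROI).
#' @param pairs List of 2-vectors of stage names; default all unordered
#'   pairs of the supplied stages, in order.
#' @param stars_from `"adjusted"` (default) or `"raw"` p-values.
#' @return Tibble: `group1`, `group2`, `n1`, `n2`, `U`, `p`, `p_adjusted`,
#'   `stars`.
#' @export
#' @examples
#' pairwise_mwu_bonferroni(list(a = c(1, 2, 3), b = c(4, 5, 6)))
pairwise_mwu_bonferroni <- function(values_by_stage, pairs = NULL,
                                    stars_from = c("adjusted", "raw")) {
  stars_from <- match.arg(stars_from)
  if (is.null(pairs)) {
    nm <- names(values_by_stage)
    pairs <- if (length(nm) >= 2) {
      apply(combn(nm, 2), 2, identity, simplify = FALSE)
    } else list()
  }
  if (length(pairs) == 0) abort("no stage pairs to test")
  family <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    g1 <- values_by_stage[[pr[1]]]
    g2 <- values_by_stage[[pr[2]]]
    if (length(g1) == 0 || length(g2) == 0) {
      abort(paste0("empty group in tested pair ", pr[1], " vs ", pr[2]))
    }
    if (length(unique(c(g1, g2))) == 1) {
      # fully tied samples carry no ordering information
      return(tibble(group1 = pr[1], group2 = pr[2],
                    n1 = length(g1), n2 = length(g2),
                    U = length(g1) * length(g2) / 2, p = 1))
    }
    has_ties <- anyDuplicated(c(g1, g2)) > 0
    exact <- !has_ties && (length(g1) + length(g2)) <= 12
    wt <- suppressWarnings(
      wilcox.test(g1, g2, alternative = "two.sided", exact = exact,
                  correct = !exact))
    tibble(group1 = pr[1], group2 = pr[2],
           n1 = length(g1), n2 = length(g2),
           U = unname(wt$statistic), p = min(wt$p.value, 1))
  })
  out <- bind_rows(rows)
  out$p_adjusted <- pmin(1, out$p * family)
  out$stars <- star_code(if (stars_from == "adjusted") out$p_adjusted
                         else out$p)
  out
}

#' Kruskal-Wallis omnibus test across stages
#'
#' Tie-corrected H statistic with a chi-square p-value on
#' `(groups - 1)` degrees of freedom; used for populations where no specific
#' stage pair is of interest.
#'
#' @param values_by_stage Named list: stage -> numeric vector.
#' @return Tibble: `H`, `df`, `p`, `n`.
#' @export
kruskal_wallis <- function(values_by_stage) {
  values_by_stage <- values_by_stage[lengths(values_by_stage) > 0]
  if (length(values_by_stage) < 2) {
    abort("Kruskal-Wallis needs at least 2 non-empty groups")
  }
  x <- unlist(values_by_stage, use.names = FALSE)
  g <- factor(rep(names(values_by_stage), lengths(values_by_stage)))
  if (length(unique(x)) == 1) {
    # fully tied data: no between-group rank variation at all
    return(tibble(H = 0, df = length(values_by_stage) - 1L, p = 1,
                  n = length(x)))
  }
  kt <- kruskal.test(x, g)
  tibble(H = unname(kt$statistic), df = unname(kt$parameter),
         p = kt$p.value, n = length(x))
}

#' Stage-wise comparisons for every population of a cohort summary
#'
#' Runs [pairwise_mwu_bonferroni()] on densities (or proportions) per
#' population, using ROIs as sample points, plus the Kruskal-Wallis omnibus
#' test per population.
#'
#' @param summaries Cohort summary from [summarize_cohort()].
#' @param measure `"density"` or `"proportion"`.
#' @param pairs Stage pairs to test; default consecutive stages plus
#'   NSQ-EAC.
#' @param stages Stage order.
#' @return List with `pairwise` (per population x pair) and `omnibus`
#'   (per population) tibbles.
#' @export
compare_stages <- function(summaries, measure = c("density", "proportion"),
                           pairs = NULL, stages = mihc_stages()) {
  measure <- match.arg(measure)
  if (is.null(pairs)) {
    pairs <- list(c("NSQ", "NDBE"), c("NDBE", "Dys"), c("Dys", "EAC"),
                  c("NSQ", "EAC"))
  }
  pops <- unique(summaries$population)
  pw <- list(); om <- list()
  for (pop in pops) {
    sub <- summaries[summaries$population == pop, ]
    if (measure == "proportion") sub <- sub[sub$proportion_defined, ]
    vals <- split(sub[[measure]], factor(sub$stage, levels = stages))
    vals <- vals[lengths(vals) > 0]
    usable <- Filter(function(pr) all(pr %in% names(vals)), pairs)
    if (length(usable) > 0) {
      res <- pairwise_mwu_bonferroni(vals, usable)
      res$population <- pop
      pw[[pop]] <- res
    }
    if (length(vals) >= 2) {
      kt <- kruskal_wallis(vals)
      kt$population <- pop
      om[[pop]] <- kt
    }
  }
  list(pairwise = bind_rows(pw) %>%
         select("population", dplyr::everything()),
       omnibus = bind_rows(om) %>%
         select("population", dplyr::everything()))
}

#' Render a report bundle from pipeline results
#'
#' Writes tidy CSVs (summaries, comparisons, enrichment aggregates) and the
#' standard figures (per-population stage plots with star annotations, the
#' group-profile heatmap, enrichment heatmaps) into a directory. Output is
#' deterministic for fixed inputs.
#'
#' @param summaries Cohort summary tibble (may be `NULL`).
#' @param comparisons Result of [compare_stages()] (may be `NULL`).
#' @param enrichment Stage-aggregated enrichment tibble (may be `NULL`).
#' @param profiles Group-profile tibble from [cluster_profiles()] (may be
#'   `NULL`).
#' @param out_dir Output directory (created).
#' @param figures Also write PDF figures (CSVs are always written).
#' @return Invisibly, the vector of files written.
#' @export
render_report <- function(summaries = NULL, comparisons = NULL,
                          enrichment = NULL, profiles = NULL,
                          out_dir, figures = TRUE) {
  if (!is.null(summaries) && nrow(summaries) > 0 &&
      anyNA(summaries$stage)) {
    abort("summaries contain missing stage labels")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  put <- function(df, name) {
    f <- file.path(out_dir, name)
    readr::write_csv(df, f, progress = FALSE)
    written <<- c(written, f)
  }
  if (!is.null(summaries)) put(summaries, "summaries.csv")
  if (!is.null(comparisons)) {
    put(comparisons$pairwise, "comparisons_pairwise.csv")
    put(comparisons$omnibus, "comparisons_omnibus.csv")
  }
  if (!is.null(enrichment)) put(enrichment, "enrichment_stage.csv")
  if (!is.null(profiles)) put(profiles, "cluster_profiles.csv")

  if (figures) {
    if (!is.null(summaries) && nrow(summaries) > 0) {
      p <- plot_density_by_stage(summaries,
                                 comparisons = comparisons$pairwise)
      f <- file.path(out_dir, "densities_by_stage.pdf")
      ggplot2::ggsave(f, p, width = 11, height = 8)
      written <- c(written, f)
    }
    if (!is.null(profiles) && nrow(profiles) > 0) {
      f <- file.path(out_dir, "cluster_profiles.pdf")
      ggplot2::ggsave(f, plot_cluster_profiles(profiles),
                      width = 8, height = 6)
      written <- c(written, f)
    }
    if (!is.null(enrichment) && nrow(enrichment) > 0) {
      f <- file.path(out_dir, "enrichment_stage.pdf")
      ggplot2::ggsave(f, plot_enrichment(enrichment), width = 9, height = 7)
      written <- c(written, f)
    }
  }
  invisible(written)
}
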