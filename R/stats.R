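#' Severity labeling from SIAS scores
#'
#' Bins a Social Interaction Anxiety Scale score (0-80) into the four
#' severity groups with half-open intervals: control `[0, 20)`, mild
#' `[20, 35)`, moderate `[35, 50)`, severe `[50, 80]`.
#'
#' @param sias Numeric score(s) in `[0, 80]`.
#' @return Factor with levels `control`, `mild`, `moderate`, `severe`.
#' @export
label_severity <- function(sias) {
  if (any(sias < 0 | sias > 80, na.rm = TRUE))
    stop("SIAS scores must lie in [0, 80]")
  cut(sias, breaks = c(0, 20, 35, 50, 80.000001), right = FALSE,
      labels = c("control", "mild", "moderate", "severe"))
}

#' One-way analysis of variance with effect size
#'
#' Classic one-way ANOVA of a numeric response over group labels,
#' reporting the F statistic, its degrees of freedom, the p-value, and the
#' eta-squared effect size `SS_between / SS_total`.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor).
#' @return List with `F`, `df` (between, within), `p`, `eta_sq`.
#' @export
oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  fit <- lm(values ~ groups)
  a <- anova(fit)
  list(F = a$`F value`[1], df = a$Df, p = a$`Pr(>F)`[1],
       eta_sq = a$`Sum Sq`[1] / sum(a$`Sum Sq`))
}

#' Pearson correlation with two-sided test
#'
#' Sample Pearson correlation with the usual two-sided t-test p-value.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r` and `p`.
#' @export
pearson_cor <- function(x, y) {
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Group-level summary tables
#'
#' Builds the group-comparison tables of the analysis: per band, group
#' means and SDs of the subject-mean PDC with one-way ANOVA columns
#' (F, p, eta-squared); the same layout per graph measure; and per-group
#' Pearson correlations between a connectivity summary and SIAS scores
#' (restricted by default to the alpha band, where the symptom-severity
#' association is assessed).
#'
#' @param subjects data.frame with one row per subject: `subject`, `group`,
#'   `sias_screen`, plus per-band mean-PDC columns named `pdc_<band>` and
#'   optionally per-band graph-measure columns named `<measure>_<band>`.
#' @param bands Band names (default the four canonical ones).
#' @param measures Graph measure column prefixes to summarize (those
#'   present are used).
#' @param cor_bands Bands for the correlation table (default `"alpha"`).
#' @return List of data.frames: `pdc` (per band x group), `graph`
#'   (per measure x band x group), `correlations` (per group).
#' @export
group_report <- function(subjects,
                         bands = c("delta", "theta", "alpha", "beta"),
                         measures = c("degree", "strength", "clustering",
                                      "local_efficiency", "modularity"),
                         cor_bands = "alpha") {
  stopifnot(all(c("group", "sias_screen") %in% names(subjects)))
  grp <- factor(subjects$group,
                levels = intersect(c("severe", "moderate", "mild", "control"),
                                   unique(subjects$group)))
  one_block <- function(col) {
    v <- subjects[[col]]
    an <- oneway_anova(v, grp)
    sds <- tapply(v, grp, sd)
    if (any(is.na(sds))) sds[is.na(sds)] <- NA  # single-subject group: flagged
    data.frame(group = levels(grp),
               mean = as.numeric(tapply(v, grp, mean)),
               sd = as.numeric(sds),
               F = an$F, p = an$p, eta_sq = an$eta_sq)
  }
  pdc_tab <- do.call(rbind, lapply(bands, function(b) {
    cbind(band = b, one_block(paste0("pdc_", b)))
  }))
  gm_cols <- unlist(lapply(measures, function(m)
    paste0(m, "_", bands)[paste0(m, "_", bands) %in% names(subjects)]))
  graph_tab <- if (length(gm_cols))
    do.call(rbind, lapply(gm_cols, function(cl) {
      parts <- strsplit(cl, "_(?=[a-z]+$)", perl = TRUE)[[1]]
      cbind(measure = parts[1], band = parts[2], one_block(cl))
    })) else NULL
  cors <- do.call(rbind, lapply(cor_bands, function(b) {
    do.call(rbind, lapply(levels(grp), function(g) {
      sel <- grp == g
      pc <- if (sum(sel) >= 3)
        pearson_cor(subjects[[paste0("pdc_", b)]][sel],
                    subjects$sias_screen[sel])
      else list(r = NA_real_, p = NA_real_)   # too few subjects: flagged
      data.frame(band = b, group = g, n = sum(sel), r = pc$r, p = pc$p)
    }))
  }))
  list(pdc = pdc_tab, graph = graph_tab, correlations = cors)
}
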