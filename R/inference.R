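#' Add orthogonal CS contrast codes to a trial table
#'
#' Two orthogonal contrasts span the 3-level CS factor: `c_cs` compares the
#' mean of both CS+ against CS- (weights CS- = -1, CSr+ = CSn+ = +1/2, so the
#' contrast applied to condition means equals mean(CS+) - mean(CS-)), and
#' `c_rn` compares CSr+ against CSn+ (weights +1, -1, 0). In the model fits
#' the CSr+/CSn+ contrast is estimated on CS+ trials only, mirroring its
#' reduced denominator degrees of freedom.
#'
#' @param table Tibble with a `cs` column (`"CS-"`, `"CSr+"`, `"CSn+"`).
#' @return The table with numeric columns `c_cs` and `c_rn` added.
#' @export
build_contrasts <- function(table) {
  w_cs <- c("CS-" = -1, "CSr+" = 0.5, "CSn+" = 0.5)
  w_rn <- c("CS-" = 0, "CSr+" = 1, "CSn+" = -1)
  dplyr::mutate(table, c_cs = unname(w_cs[.data$cs]),
                c_rn = unname(w_rn[.data$cs]))
}

effect_row <- function(tab, term, label) {
  i <- match(term, rownames(tab))
  tibble::tibble(effect = label,
                 F = tab[i, "F value"],
                 df_num = tab[i, "NumDF"],
                 df_den = tab[i, "DenDF"],
                 p = tab[i, "Pr(>F)"])
}

#' Trial-level linear mixed-effects models with the study's contrasts
#'
#' Fits `response ~ drug * CS * time + (1 | participant)` by REML with
#' Satterthwaite denominator degrees of freedom, using sum-to-zero factor
#' coding and Type III F tests. Two models are fitted: the full model with CS
#' pooled into CS+ vs CS-, and a CS+-only model for the CSr+ vs CSn+
#' contrast (which therefore has fewer denominator df). Unbalanced data —
#' excluded trials — are unproblematic for this model.
#'
#' @param table Tibble with columns `participant`, `group` (`"placebo"` /
#'   `"drug"`), `cs`, `trial`, and the response.
#' @param response Response column name.
#' @param time Time coding: `"none"` (acquisition-style), `"across_cs"`
#'   (trial number across CS, retention) or `"within_cs"` (trial counter
#'   within each CS, relearning); entered as a categorical factor.
#' @param covariates Optional character vector of covariate columns added as
#'   main effects and interactions with the CS contrast.
#' @param df_method `"satterthwaite"` (default) or `"residual"` fallback.
#' @return A `fear_lme` object; `tidy()` returns the effect table (effect,
#'   F, df_num, df_den, p).
#' @export
fit_lme <- function(table, response = "amplitude",
                    time = c("none", "across_cs", "within_cs"),
                    covariates = NULL,
                    df_method = c("satterthwaite", "residual")) {
  time <- match.arg(time)
  df_method <- match.arg(df_method)
  stopifnot(all(c("participant", "group", "cs", "trial") %in% names(table)))
  d <- dplyr::filter(table, is.finite(.data[[response]]))
  if (dplyr::n_distinct(d$participant[d$group == "placebo"]) < 2 ||
      dplyr::n_distinct(d$participant[d$group == "drug"]) < 2) {
    stop("need at least 2 participants per group", call. = FALSE)
  }
  d$.y <- d[[response]]
  d$drug <- factor(d$group, levels = c("placebo", "drug"))
  d$csp <- factor(ifelse(d$cs == "CS-", "CS-", "CS+"), levels = c("CS-", "CS+"))
  d <- switch(time,
    none = dplyr::mutate(d, t = NULL),
    across_cs = dplyr::mutate(d, t = factor(.data$trial)),
    within_cs = d |>
      dplyr::group_by(.data$participant, .data$cs) |>
      dplyr::mutate(t = factor(dplyr::row_number())) |>
      dplyr::ungroup()
  )
  has_t <- time != "none"
  cov_part <- if (length(covariates)) {
    paste0(" + ", paste(covariates, collapse = " + "), " + ",
           paste(covariates, "csp", sep = ":", collapse = " + "))
  } else ""
  rhs_full <- if (has_t) "drug * csp * t" else "drug * csp"
  f_full <- stats::as.formula(paste0(".y ~ ", rhs_full, cov_part,
                                     " + (1 | participant)"))
  fit_one <- function(formula, data) {
    opts <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(opts))
    m <- lmerTest::lmer(formula, data = data,
                        control = lme4::lmerControl(calc.derivs = FALSE))
    a <- if (df_method == "satterthwaite") {
      tryCatch(stats::anova(m, type = 3), error = function(e) NULL)
    }
    if (is.null(a) || anyNA(a[["DenDF"]])) {
      # residual-df fallback: lme4 F values with df = n - p
      raw <- as.matrix(stats::anova(m, type = 3, ddf = "lme4"))
      den <- stats::nobs(m) - length(lme4::fixef(m))
      a <- cbind(raw,
                 NumDF = raw[, "npar"],
                 DenDF = den,
                 `Pr(>F)` = stats::pf(raw[, "F value"], raw[, "npar"], den,
                                      lower.tail = FALSE))
      rownames(a) <- rownames(raw)
    }
    list(model = m, anova = as.matrix(a))
  }
  full <- fit_one(f_full, d)

  d_plus <- dplyr::filter(d, .data$cs != "CS-")
  both_csplus <- dplyr::n_distinct(d_plus$cs) == 2
  plus <- NULL
  if (both_csplus) {
    d_plus$csr <- factor(d_plus$cs, levels = c("CSn+", "CSr+"))
    rhs_plus <- if (has_t) "drug * csr * t" else "drug * csr"
    f_plus <- stats::as.formula(paste0(".y ~ ", rhs_plus,
                                       " + (1 | participant)"))
    plus <- fit_one(f_plus, d_plus)
  }

  ta <- full$anova
  tb <- if (both_csplus) plus$anova
  rows <- list(
    effect_row(ta, "drug", "Drug"),
    effect_row(ta, "csp", "CS+ vs CS-"),
    effect_row(ta, "drug:csp", "Drug × (CS+ vs CS-)")
  )
  if (has_t) {
    rows <- c(rows, list(
      effect_row(ta, "t", "Trial"),
      effect_row(ta, "drug:t", "Drug × trial"),
      effect_row(ta, "csp:t", "Trial × (CS+ vs CS-)"),
      effect_row(ta, "drug:csp:t", "Drug × trial × (CS+ vs CS-)")
    ))
  }
  if (both_csplus) {
    rows <- c(rows, list(
      effect_row(tb, "csr", "CSr+ vs CSn+"),
      effect_row(tb, "drug:csr", "Drug × (CSr+ vs CSn+)")
    ))
    if (has_t) {
      rows <- c(rows, list(
        effect_row(tb, "drug:csr:t", "Drug × trial × (CSr+ vs CSn+)")
      ))
    }
  }
  if (length(covariates)) {
    for (cv in covariates) {
      rows <- c(rows, list(
        effect_row(ta, cv, cv),
        effect_row(ta, paste0("csp:", cv), paste0(cv, " × (CS+ vs CS-)"))
      ))
    }
  }
  effects <- dplyr::bind_rows(rows)
  singular <- lme4::isSingular(full$model)
  structure(list(effects = effects, model_full = full$model,
                 model_csplus = plus$model, time = time,
                 df_method = df_method, singular = singular,
                 n_obs = nrow(d),
                 n_participants = dplyr::n_distinct(d$participant)),
            class = "fear_lme")
}

#' @export
print.fear_lme <- function(x, ...) {
  cat(sprintf("<fear_lme> %d obs, %d participants, time = %s%s\n",
              x$n_obs, x$n_participants, x$time,
              if (x$singular) " (singular fit)" else ""))
  print(as.data.frame(x$effects), digits = 3)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.fear_lme <- function(x, ...) x$effects

#' @export
glance.fear_lme <- function(x, ...) {
  tibble::tibble(nobs = x$n_obs, n_participants = x$n_participants,
                 sigma = stats::sigma(x$model_full), singular = x$singular,
                 df_method = x$df_method)
}

#' Conditionwise repeated-measures ANOVA with pooled error
#'
#' Standard repeated-measures ANOVA on one amplitude per participant and
#' condition: between factor group, within factor CS split into the two
#' orthogonal contrasts (CS+ vs CS- and CSr+ vs CSn+), each tested against
#' the pooled within-participant error variance.
#'
#' @param cond_table Tibble with columns `participant`, `group`, `cs`,
#'   `amplitude` (one row per participant x condition).
#' @return A `fear_anova` object; `tidy()` returns the effect table.
#' @export
fit_rm_anova <- function(cond_table) {
  d <- cond_table
  d$drug <- factor(d$group, levels = c("placebo", "drug"))
  lv <- intersect(CS_LEVELS, unique(d$cs))
  d$cs <- factor(d$cs, levels = lv)
  d$participant <- factor(d$participant)
  one_group <- nlevels(droplevels(d$drug)) < 2
  opts <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(opts))
  grab <- function(tab, pattern, label) {
    i <- grep(pattern, rownames(tab), fixed = TRUE)[1]
    j <- nrow(tab)  # residual row
    tibble::tibble(effect = label, F = tab[i, "F value"],
                   df_num = tab[i, "Df"], df_den = tab[j, "Df"],
                   p = tab[i, "Pr(>F)"])
  }
  rhs <- if (one_group) "cs" else "drug * cs"
  f <- stats::as.formula(paste("amplitude ~", rhs, "+ Error(participant)"))
  if (length(lv) == 3) {
    stats::contrasts(d$cs) <- cbind("CS+ vs CS-" = c(-2 / 3, 1 / 3, 1 / 3),
                                    "CSr+ vs CSn+" = c(0, 1, -1))
    m <- stats::aov(f, data = d)
    split <- list("CS+ vs CS-" = 1, "CSr+ vs CSn+" = 2)
    s <- summary(m, split = list(cs = split, "drug:cs" = split))
    within <- s[["Error: Within"]][[1]]
    effects <- dplyr::bind_rows(
      grab(within, "cs: CS+ vs CS-", "CS+ vs CS-"),
      grab(within, "cs: CSr+ vs CSn+", "CSr+ vs CSn+")
    )
    if (!one_group) {
      effects <- dplyr::bind_rows(
        grab(s[["Error: participant"]][[1]], "drug", "Drug"),
        effects,
        grab(within, "drug:cs: CS+ vs CS-", "Drug × (CS+ vs CS-)"),
        grab(within, "drug:cs: CSr+ vs CSn+", "Drug × (CSr+ vs CSn+)")
      )
    }
  } else {
    # two conditions: a single 1-df within contrast (F = squared paired t
    # in the one-group case)
    lab <- paste(rev(lv), collapse = " vs ")
    m <- stats::aov(f, data = d)
    s <- summary(m)
    within <- s[["Error: Within"]][[1]]
    effects <- grab(within, "cs", lab)
    if (!one_group) {
      effects <- dplyr::bind_rows(
        grab(s[["Error: participant"]][[1]], "drug", "Drug"),
        effects,
        grab(within, "drug:cs", paste0("Drug × (", lab, ")"))
      )
    }
  }
  structure(list(effects = effects, model = m,
                 n_participants = dplyr::n_distinct(d$participant)),
            class = "fear_anova")
}

#' @export
print.fear_anova <- function(x, ...) {
  cat(sprintf("<fear_anova> %d participants\n", x$n_participants))
  print(as.data.frame(x$effects), digits = 3)
  invisible(x)
}

#' @export
tidy.fear_anova <- function(x, ...) x$effects

#' @export
glance.fear_anova <- function(x, ...) {
  tibble::tibble(n_participants = x$n_participants)
}

#' Group comparison t test
#'
#' Independent-samples (pooled-variance) or paired two-tailed t test, as used
#' for control measures, without multiple-comparison correction.
#'
#' @param values Numeric vector (per participant).
#' @param labels Two-level grouping vector (independent test), or for
#'   `paired = TRUE` a second numeric vector of paired values.
#' @param paired Paired test?
#' @return One-row tibble: `t`, `df`, `p`, `estimate`.
#' @export
compare_groups <- function(values, labels, paired = FALSE) {
  if (paired) {
    ht <- stats::t.test(values, labels, paired = TRUE)
  } else {
    labels <- factor(labels)
    stopifnot(nlevels(labels) == 2)
    ht <- stats::t.test(values[labels == levels(labels)[1]],
                        values[labels == levels(labels)[2]],
                        var.equal = TRUE)
  }
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value,
                 estimate = if (paired) unname(ht$estimate) else
                   unname(diff(rev(ht$estimate))))
}

#' Fraction of drug cleared after a given time
#'
#' First-order elimination: `1 - 2^(-elapsed / half_life)`. With a ~16 h
#' half-life, more than 99.9% of a dose is cleared after 7 days.
#'
#' @param half_life_h Elimination half-life in hours.
#' @param elapsed_h Time since ingestion in hours.
#' @return Cleared fraction in `[0, 1)`.
#' @examples
#' clearance_fraction(16, 168) # > 0.999
#' @export
clearance_fraction <- function(half_life_h, elapsed_h) {
  stopifnot(half_life_h > 0, elapsed_h >= 0)
  1 - 2^(-elapsed_h / half_life_h)
}
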