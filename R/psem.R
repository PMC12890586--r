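#' Piecewise path model specification
#'
#' A piecewise structural equation model is a causal DAG fitted as a set of
#' component linear regressions, one per endogenous variable. The default
#' specification models interval-corrected mortality rate and stem abundance
#' change as intermediate demographic responses and species richness change
#' as the final response, with six climate covariates, landscape integrity
#' and the census time frame as exogenous drivers; identification-effort
#' change enters only the richness component (a sampling artefact cannot
#' cause demography).
#'
#' @param formulas Named list: response -> character vector of predictors.
#' @param group Name of the grouping column (default `"region"`).
#' @return Object of class `path_model_spec` with elements `formulas`,
#'   `group`, `responses`, `exogenous`, `vars` and the igraph `dag`.
#' @export
path_model_spec <- function(formulas = default_sem_formulas(),
                            group = "region") {
  stopifnot(is.list(formulas), length(names(formulas)) == length(formulas))
  edges <- do.call(rbind, lapply(names(formulas), function(resp) {
    cbind(from = formulas[[resp]], to = resp)
  }))
  dag <- igraph::graph_from_edgelist(edges, directed = TRUE)
  if (!igraph::is_dag(dag)) stop("path model must be acyclic")
  vars <- igraph::topo_sort(dag)$name
  structure(list(formulas = formulas, group = group,
                 responses = names(formulas),
                 exogenous = setdiff(vars, names(formulas)),
                 vars = vars, dag = dag),
            class = "path_model_spec")
}

#' @rdname path_model_spec
#' @export
default_sem_formulas <- function() {
  env <- c("max_temperature", "annual_precipitation",
           "precipitation_seasonality", "temperature_change",
           "precipitation_change", "seasonality_change",
           "landscape_integrity")
  list(
    mortality_rate = c(env, "time_frame"),
    stem_abundance_change = c(env, "time_frame", "mortality_rate"),
    richness_change = c(env, "time_frame", "id_effort_change",
                        "mortality_rate", "stem_abundance_change"))
}

#' @export
print.path_model_spec <- function(x, ...) {
  cat("<path_model_spec> group =", x$group, "\n")
  for (r in x$responses) {
    cat(" ", r, "~", paste(x$formulas[[r]], collapse = " + "), "\n")
  }
  invisible(x)
}

#' Fit one SEM component regression
#'
#' Ordinary least squares with a variance-inflation guard (default VIF < 4)
#' and standardized coefficients `beta_std = beta * sd(x) / sd(y)` — the
#' "effects" compared across paths. For a single-predictor model the
#' standardized coefficient equals the Pearson correlation.
#'
#' @param response Response column name.
#' @param predictors Character vector of predictor column names.
#' @param data Data frame of complete cases.
#' @param max_vif VIF threshold (default 4); breach errors naming the
#'   offending predictors.
#' @return List `fit` (lm), `coefficients` tibble (`term, estimate,
#'   std_estimate, se, p`), `r_squared`, `vif`, `shapiro_p`.
#' @export
fit_component <- function(response, predictors, data, max_vif = 4) {
  data <- data[complete.cases(data[, c(response, predictors)]), , drop = FALSE]
  if (length(predictors) > 1) vif <- vif_check(data[, predictors], max_vif)
  else vif <- setNames(1, predictors)
  fit <- lm(stats::reformulate(predictors, response), data = data)
  if (any(is.na(coef(fit)))) stop("rank-deficient component fit for ", response)
  sm <- summary(fit)
  sds <- vapply(data[, predictors, drop = FALSE], sd, numeric(1))
  sdy <- sd(data[[response]])
  est <- coef(fit)[predictors]
  shapiro_p <- if (nrow(data) >= 3 && nrow(data) <= 5000) {
    stats::shapiro.test(stats::residuals(fit))$p.value
  } else NA_real_
  list(fit = fit,
       coefficients = tibble::tibble(
         term = predictors,
         estimate = unname(est),
         std_estimate = unname(est * sds / sdy),
         se = unname(sm$coefficients[predictors, 2]),
         p = unname(sm$coefficients[predictors, 4])),
       r_squared = sm$r.squared, vif = vif, shapiro_p = shapiro_p)
}

# F-test for the group interaction of one predictor within a component
interaction_ftest <- function(response, predictors, x, group, data) {
  base <- lm(stats::reformulate(c(predictors, group), response), data = data)
  full <- lm(stats::reformulate(c(predictors, group,
                                  paste(group, x, sep = ":")), response),
             data = data)
  anova(base, full)[2, "Pr(>F)"]
}

#' Fit a multigroup piecewise SEM
#'
#' Each path is tested for heterogeneity across groups with a nested-model F
#' test of the path-by-group interaction (full set of group dummies). When
#' the interaction is not significant at `alpha` the path is *constrained*:
#' a single pooled coefficient (from the component fit with group
#' intercepts) is reported for all groups. Otherwise the path is *free* and
#' per-group component fits are reported. Directed-separation claims are
#' tested with group intercepts, and the global fit summarised by Fisher's C.
#' Standardization uses pooled standard deviations for constrained paths and
#' within-group standard deviations for free paths.
#'
#' @param spec A [path_model_spec()].
#' @param data Analysis table containing every model variable and the group
#'   column.
#' @param alpha Significance level for the interaction test (default 0.05).
#' @param max_vif VIF guard forwarded to the component fits.
#' @return Object of class `path_fit`: `paths` tibble (`component, term,
#'   constrained, region, estimate, std_estimate, p, interaction_p`),
#'   per-component `r_squared`, d-separation `claims`, `fisher_c`
#'   (`C, df, p`), `groups`, `spec`.
#' @export
multigroup_fit <- function(spec, data, alpha = 0.05, max_vif = 4) {
  stopifnot(inherits(spec, "path_model_spec"))
  group <- spec$group
  need <- c(spec$vars, group)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("data is missing model variable(s): ",
         paste(missing_cols, collapse = ", "))
  }
  data <- data[complete.cases(data[, need]), , drop = FALSE]
  data[[group]] <- factor(data[[group]])
  groups <- levels(data[[group]])
  multi <- length(groups) > 1
  biggest <- max(vapply(spec$formulas, length, integer(1)))
  n_by_group <- table(data[[group]])
  if (multi && any(n_by_group <= biggest + 2)) {
    stop("group(s) with too few rows for the largest component: ",
         paste(names(n_by_group)[n_by_group <= biggest + 2], collapse = ", "))
  }
  paths <- list()
  r2 <- numeric(0)
  for (resp in spec$responses) {
    preds <- spec$formulas[[resp]]
    vif_check(data[, preds], max_vif)
    pooled_terms <- if (multi) c(preds, group) else preds
    pooled <- lm(stats::reformulate(pooled_terms, resp), data = data)
    sm <- summary(pooled)
    r2[resp] <- sm$r.squared
    sds <- vapply(data[, preds, drop = FALSE], sd, numeric(1))
    sdy <- sd(data[[resp]])
    per_group_fit <- if (multi) {
      lapply(groups, function(g) {
        fit_component(resp, preds, data[data[[group]] == g, , drop = FALSE],
                      max_vif = Inf)
      })
    } else NULL
    if (!is.null(per_group_fit)) names(per_group_fit) <- groups
    for (x in preds) {
      int_p <- if (multi) interaction_ftest(resp, preds, x, group, data)
               else NA_real_
      constrained <- !multi || int_p > alpha
      if (constrained) {
        paths[[length(paths) + 1]] <- tibble::tibble(
          component = resp, term = x, constrained = TRUE, region = "all",
          estimate = unname(coef(pooled)[x]),
          std_estimate = unname(coef(pooled)[x] * sds[x] / sdy),
          p = sm$coefficients[x, 4], interaction_p = int_p)
      } else {
        for (g in groups) {
          cf <- per_group_fit[[g]]$coefficients
          row <- cf[cf$term == x, ]
          paths[[length(paths) + 1]] <- tibble::tibble(
            component = resp, term = x, constrained = FALSE, region = g,
            estimate = row$estimate, std_estimate = row$std_estimate,
            p = row$p, interaction_p = int_p)
        }
      }
    }
  }
  claims <- dsep_basis_set(spec)
  claim_p <- numeric(nrow(claims))
  if (nrow(claims) > 0) {
    for (i in seq_len(nrow(claims))) {
      dep <- claims$dependent[i]
      terms <- c(claims$conditioning[[i]],
                 if (multi) group, claims$independent[i])
      fit <- lm(stats::reformulate(terms, dep), data = data)
      claim_p[i] <- summary(fit)$coefficients[claims$independent[i], 4]
    }
  }
  claims$p <- claim_p
  fc <- fisher_c(claim_p)
  structure(list(paths = dplyr::bind_rows(paths), r_squared = r2,
                 claims = claims, fisher_c = fc, groups = groups,
                 spec = spec, alpha = alpha, n = nrow(data)),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  npath <- nrow(unique(x$paths[, c("component", "term")]))
  ncon <- sum(x$paths$constrained[!duplicated(x$paths[, c("component", "term")])])
  cat("<path_fit> ", length(x$spec$responses), " components, ", npath,
      " paths (", ncon, " constrained), ", length(x$groups), " group(s)\n",
      sep = "")
  cat("  Fisher's C = ", round(x$fisher_c$C, 3), ", df = ", x$fisher_c$df,
      ", P = ", round(x$fisher_c$p, 3), "\n", sep = "")
  cat("  R-squared:", paste(names(x$r_squared),
                            round(x$r_squared, 2), collapse = ", "), "\n")
  invisible(x)
}

#' Directed-separation basis set
#'
#' The independence claims implied by the missing edges of the DAG: every
#' non-adjacent variable pair with at least one endogenous member yields one
#' claim, tested by regressing the downstream (endogenous) member on the
#' other variable plus its own parents. Exogenous-exogenous pairs are
#' excluded (their covariances are free).
#'
#' @param spec A [path_model_spec()].
#' @return Tibble `dependent, independent, conditioning` (list column of the
#'   dependent's parents); zero rows for a saturated model.
#' @export
dsep_basis_set <- function(spec) {
  vars <- spec$vars
  topo_rank <- setNames(seq_along(vars), vars)
  parents <- function(v) if (v %in% spec$responses) spec$formulas[[v]] else character(0)
  out <- list()
  for (i in seq_along(vars)) {
    for (j in seq_len(i - 1)) {
      u <- vars[j]; v <- vars[i]
      if (u %in% parents(v) || v %in% parents(u)) next
      if (!(u %in% spec$responses) && !(v %in% spec$responses)) next
      # dependent = the downstream endogenous member
      dep <- if (v %in% spec$responses) v else u
      ind <- setdiff(c(u, v), dep)
      out[[length(out) + 1]] <- tibble::tibble(
        dependent = dep, independent = ind,
        conditioning = list(parents(dep)))
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(dependent = character(0),
                          independent = character(0),
                          conditioning = list()))
  }
  dplyr::bind_rows(out)
}

#' Fisher's C statistic
#'
#' Combines the P values of the directed-separation tests:
#' `C = -2 * sum(log p_i)`, chi-squared with `2k` degrees of freedom under
#' the null that the DAG's missing edges are consistent with the data; a
#' large P value (> 0.05) indicates good fit. An empty basis set (saturated
#' model) gives `C = 0, p = 1`.
#'
#' @param p Vector of claim P values in `(0, 1]`.
#' @return List `C, df, p`.
#' @export
fisher_c <- function(p) {
  if (length(p) == 0) return(list(C = 0, df = 0, p = 1))
  stopifnot(all(p > 0 & p <= 1))
  C <- -2 * sum(log(p))
  df <- 2 * length(p)
  list(C = C, df = df, p = pchisq(C, df, lower.tail = FALSE))
}

# lookup std estimate and p of a path for one region ("all" rows apply to
# every region); returns c(std, p) or NULL when the path is absent
path_lookup <- function(paths, term, component, region) {
  row <- paths[paths$term == term & paths$component == component &
                 (paths$region == region | paths$region == "all"), , drop = FALSE]
  if (nrow(row) == 0) return(NULL)
  c(std = unname(row$std_estimate[1]), p = unname(row$p[1]))
}

#' Direct, indirect and total effects on the final response
#'
#' For each predictor and group, the direct effect is its standardized
#' coefficient in the final-response component when significant
#' (`p <= alpha`, else 0). Indirect effects are the products of the
#' standardized coefficients along each of the three indirect pathways (via
#' stem abundance change, via mortality rate, via mortality then stem
#' abundance change), each computed only when every link on the pathway is
#' significant, else contributing exactly 0; the total indirect effect is
#' their sum and the total effect is direct plus total indirect.
#' Constrained paths contribute their pooled estimate to every group.
#'
#' @param fit A [multigroup_fit()] result.
#' @param alpha Per-link significance threshold (default 0.05).
#' @return Tibble `region, predictor, direct, indirect_via_stem,
#'   indirect_via_mortality, indirect_via_mortality_then_stem,
#'   total_indirect, total`.
#' @export
effect_decomposition <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "path_fit"))
  spec <- fit$spec
  final <- spec$responses[length(spec$responses)]
  mid <- spec$responses[spec$responses != final]
  mort <- grep("mortality", mid, value = TRUE)[1]
  stem <- setdiff(mid, mort)[1]
  paths <- fit$paths
  sig <- function(v) if (is.null(v) || is.na(v["p"]) || v["p"] > alpha) 0 else unname(v["std"])
  out <- list()
  for (region in fit$groups) {
    b_stem_rich <- sig(path_lookup(paths, stem, final, region))
    b_mort_rich <- sig(path_lookup(paths, mort, final, region))
    b_mort_stem <- sig(path_lookup(paths, mort, stem, region))
    for (pred in spec$formulas[[final]]) {
      direct <- sig(path_lookup(paths, pred, final, region))
      a_stem <- if (pred %in% c(stem, mort)) NULL else path_lookup(paths, pred, stem, region)
      a_mort <- if (pred %in% c(stem, mort)) NULL else path_lookup(paths, pred, mort, region)
      via_stem <- if (pred == mort) b_mort_stem * b_stem_rich
                  else sig(a_stem) * b_stem_rich
      via_mort <- if (pred %in% c(stem, mort)) 0 else sig(a_mort) * b_mort_rich
      via_mort_stem <- if (pred %in% c(stem, mort)) 0
                       else sig(a_mort) * b_mort_stem * b_stem_rich
      total_ind <- via_stem + via_mort + via_mort_stem
      out[[length(out) + 1]] <- tibble::tibble(
        region = region, predictor = pred, direct = direct,
        indirect_via_stem = via_stem, indirect_via_mortality = via_mort,
        indirect_via_mortality_then_stem = via_mort_stem,
        total_indirect = total_ind, total = direct + total_ind)
    }
  }
  dplyr::bind_rows(out)
}

#' Export the fitted path diagram as DOT
#'
#' Writes a Graphviz DOT description of the DAG with edges labelled by the
#' (pooled or per-group mean) standardized coefficient, solid for positive
#' and dashed for negative effects.
#'
#' @param fit A [multigroup_fit()] result.
#' @param path Output file path.
#' @export
write_path_dot <- function(fit, path) {
  agg <- fit$paths |>
    dplyr::group_by(.data$component, .data$term) |>
    dplyr::summarise(std = mean(.data$std_estimate),
                     constrained = .data$constrained[1], .groups = "drop")
  lines <- c("digraph sem {", "  rankdir=LR;")
  for (i in seq_len(nrow(agg))) {
    lines <- c(lines, sprintf(
      '  "%s" -> "%s" [label="%.2f%s", style=%s];',
      agg$term[i], agg$component[i], agg$std[i],
      ifelse(agg$constrained[i], "", " (free)"),
      ifelse(agg$std[i] >= 0, "solid", "dashed")))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
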