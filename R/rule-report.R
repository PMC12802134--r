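#' Discretize a fitted model into a rule set
#'
#' Binarizes the annealed network at a cut point (default 0.5): a rule is
#' kept iff its relaxed selector value exceeds the cut, a detector iff its
#' selector value exceeds the cut, and a feature is a member of a detector
#' iff its soft-inclusion weight exceeds the cut at the final temperatures
#' (equivalently, its embedded distance to the center is within the
#' radius). Degenerate cases keep the discretization faithful to the
#' network's zero-temperature limit: a selected rule with no selected
#' detectors is the empty conjunction (always true), so its weight folds
#' into the intercept; a selected metabolite detector with no member inside
#' the radius keeps its single nearest feature (the limit of the weighted
#' mean); a selected taxa detector with no members aggregates to zero and
#' makes its rule constant-false when its threshold is non-negative.
#'
#' @param fit an `mm_fit` from [fit_rules()] or [multi_seed_fit()].
#' @param cut selection/membership cut point in (0, 1).
#' @return object of class `mm_ruleset`: `rules` (list of rules, each with
#'   `detectors`, `beta`, `odds_factor`) and `intercept`.
#' @export
extract_rules <- function(fit, cut = 0.5) {
  p <- fit$params; hp <- fit$hp; tm <- fit$final_temps
  q <- selector_value(p$rule_logits, tm$tau_q)
  zM <- selector_value(p$det_logits_M, tm$tau_z)  # K x J
  zT <- selector_value(p$det_logits_T, tm$tau_z)  # K x L
  rules <- list()
  intercept <- p$beta0
  for (k in seq_len(hp$K)) {
    if (q[k] <= cut) next
    detectors <- list()
    n_selected <- 0L
    always_false <- FALSE
    for (j in seq_len(hp$J)) {
      if (zM[k, j] <= cut) next
      n_selected <- n_selected + 1L
      row <- (k - 1) * hp$J + j
      d <- sqrt(colSums((t(fit$EM) - p$centers_M[row, ])^2))
      u <- sigmoid((p$radii_M[row] - d) / tm$tau_u)
      members <- fit$feature_ids_M[u > cut]
      if (length(members) == 0) {
        # zero-temperature limit of the weighted mean: the feature nearest
        # the center dominates even outside the radius
        members <- fit$feature_ids_M[which.min(d)]
      }
      detectors <- c(detectors, list(list(
        modality = "metabolite", member_ids = members,
        threshold = p$eta_M[row], aggregate = "mean standardized level",
        direction = "greater than")))
    }
    for (l in seq_len(hp$L)) {
      if (zT[k, l] <= cut) next
      n_selected <- n_selected + 1L
      row <- (k - 1) * hp$L + l
      d <- sqrt(colSums((t(fit$ET) - p$centers_T[row, ])^2))
      u <- sigmoid((p$radii_T[row] - d) / tm$tau_u)
      members <- fit$feature_ids_T[u > cut]
      if (length(members) == 0) {
        # empty taxa detector aggregates to 0: constant true iff eta < 0
        if (p$eta_T[row] >= 0) always_false <- TRUE
        next
      }
      detectors <- c(detectors, list(list(
        modality = "taxa", member_ids = members,
        threshold = p$eta_T[row], aggregate = "summed relative abundance",
        direction = "greater than")))
    }
    if (always_false) next
    if (n_selected == 0L || length(detectors) == 0) {
      # empty conjunction is true: the rule fires for every subject, so its
      # weight is a constant log-odds offset
      intercept <- intercept + p$beta[k]
      next
    }
    rules <- c(rules, list(list(detectors = detectors, beta = p$beta[k],
                                odds_factor = exp(p$beta[k]))))
  }
  if (length(rules) == 0) {
    warning("no rule survived selection; intercept-only model")
  }
  structure(list(rules = rules, intercept = intercept), class = "mm_ruleset")
}

#' @export
print.mm_ruleset <- function(x, ...) {
  cat(render_rules(x), sep = "\n")
  invisible(x)
}

#' Evaluate a discretized rule set on data
#'
#' Hard boolean evaluation: a detector fires when its aggregate over its
#' member features exceeds its threshold; a rule fires when all its
#' detectors fire; the log odds are the intercept plus the weights of the
#' firing rules.
#'
#' @param rs an `mm_ruleset`.
#' @param taxa,metab aligned feature tables (`relative_abundance` /
#'   `log_standardized`).
#' @return tibble (`subject_id`, `p_case`, `class`).
#' @export
evaluate_ruleset <- function(rs, taxa, metab) {
  n <- nrow(taxa$values)
  f <- rep(rs$intercept, n)
  for (rule in rs$rules) {
    active <- rep(TRUE, n)
    for (d in rule$detectors) {
      agg <- if (d$modality == "metabolite") {
        rowMeans(metab$values[, d$member_ids, drop = FALSE])
      } else {
        rowSums(taxa$values[, d$member_ids, drop = FALSE])
      }
      active <- active & (agg > d$threshold)
    }
    f <- f + rule$beta * active
  }
  tibble::tibble(subject_id = rownames(taxa$values),
                 p_case = sigmoid(f), class = as.integer(f > 0))
}

#' Render a rule set as English text
#'
#' One paragraph per rule, rules ordered by decreasing `|beta|`, members
#' lexicographic: "IF <aggregate> of \{members\} > <threshold> \[AND ...\]
#' THEN odds of <case label> x<factor> (increased|decreased by ...-fold)".
#'
#' @param rs an `mm_ruleset`.
#' @param case_label display name of the positive class.
#' @return character vector of paragraphs.
#' @export
render_rules <- function(rs, case_label = "case") {
  if (length(rs$rules) == 0) {
    return(sprintf(
      "intercept-only model: no rule survived selection (baseline odds %.3g)",
      exp(rs$intercept)))
  }
  ord <- order(-abs(vapply(rs$rules, function(r) r$beta, numeric(1))))
  vapply(rs$rules[ord], function(rule) {
    clauses <- vapply(rule$detectors, function(d) {
      sprintf("%s of {%s} > %.4g", d$aggregate,
              paste(sort(d$member_ids), collapse = ", "), d$threshold)
    }, character(1))
    dir_word <- if (rule$beta >= 0) "increased" else "decreased"
    fold <- if (rule$beta >= 0) rule$odds_factor else 1 / rule$odds_factor
    sprintf("IF %s THEN odds of %s x%.3g (%s by %.3g-fold)",
            paste(clauses, collapse = " AND "), case_label,
            signif(rule$odds_factor, 3), dir_word, signif(fold, 3))
  }, character(1))
}

#' Export / import a rule set as structured JSON
#'
#' Lossless round trip: `import_rules(export_rules(rs, path))` reproduces
#' the rule set exactly.
#'
#' @param rs an `mm_ruleset`.
#' @param path output (input) file path.
#' @return `export_rules()` returns `path` invisibly; `import_rules()`
#'   returns the `mm_ruleset`.
#' @export
export_rules <- function(rs, path) {
  payload <- list(
    intercept = rs$intercept,
    rules = lapply(rs$rules, function(rule) {
      list(beta = rule$beta, odds_factor = rule$odds_factor,
           detectors = lapply(rule$detectors, function(d) {
             list(modality = d$modality,
                  member_ids = as.list(d$member_ids),
                  threshold = d$threshold, aggregate = d$aggregate,
                  direction = d$direction)
           }))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname export_rules
#' @export
import_rules <- function(path) {
  payload <- jsonlite::read_json(path)
  rules <- lapply(payload$rules, function(rule) {
    list(detectors = lapply(rule$detectors, function(d) {
      list(modality = d$modality,
           member_ids = as.character(unlist(d$member_ids)),
           threshold = d$threshold, aggregate = d$aggregate,
           direction = d$direction)
    }), beta = rule$beta, odds_factor = rule$odds_factor)
  })
  structure(list(rules = rules, intercept = payload$intercept),
            class = "mm_ruleset")
}

# ---- broom-style methods --------------------------------------------------

#' Tidy a rule set or fitted model
#'
#' @param x an `mm_ruleset` or `mm_fit`.
#' @param ... passed to [extract_rules()] for `mm_fit`.
#' @return tibble with one row per detector: `rule`, `beta`, `odds_factor`,
#'   `detector`, `modality`, `aggregate`, `threshold`, `n_members`,
#'   `members` (list column).
#' @method tidy mm_ruleset
#' @export
tidy.mm_ruleset <- function(x, ...) {
  if (length(x$rules) == 0) {
    return(tibble::tibble(rule = integer(), beta = double(),
                          odds_factor = double(), detector = integer(),
                          modality = character(), aggregate = character(),
                          threshold = double(), n_members = integer(),
                          members = list()))
  }
  purrr::imap_dfr(x$rules, function(rl, k) {
    purrr::imap_dfr(rl$detectors, function(d, i) {
      tibble::tibble(rule = k, beta = rl$beta,
                     odds_factor = rl$odds_factor, detector = i,
                     modality = d$modality, aggregate = d$aggregate,
                     threshold = d$threshold,
                     n_members = length(d$member_ids),
                     members = list(sort(d$member_ids)))
    })
  })
}

#' @rdname tidy.mm_ruleset
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  tidy.mm_ruleset(extract_rules(x, ...))
}

#' One-row model summary
#'
#' @param x an `mm_fit`.
#' @param ... unused.
#' @return tibble with `final_loss`, `converged`, `epochs`, `seed`,
#'   `n_rules`, `n_subjects`.
#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  rs <- suppressWarnings(extract_rules(x))
  tibble::tibble(final_loss = x$final_loss, converged = x$converged,
                 epochs = length(x$loss_trace), seed = x$seed,
                 n_rules = length(rs$rules), n_subjects = x$n_subjects)
}

#' Plot the training loss trace
#'
#' @param object an `mm_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot mm_fit
#' @export
autoplot.mm_fit <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$loss_trace),
                       loss = object$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "epoch", y = "negative log posterior",
                  title = "MAP training loss") +
    ggplot2::theme_minimal()
}

#' Plot cross-validated predictions
#'
#' Held-out case probabilities by true class, one facet per fold.
#'
#' @param object an `mm_cv`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot mm_cv
#' @export
autoplot.mm_cv <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = factor(.data$label), y = .data$p_case)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, colour = "steelblue") +
    ggplot2::facet_wrap(~fold, nrow = 1) +
    ggplot2::labs(x = "true class", y = "held-out P(case)",
                  title = sprintf("Cross-validated predictions (mean AUC %.2f)",
                                  object$mean_auc)) +
    ggplot2::theme_minimal()
}
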