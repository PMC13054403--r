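#' Backward elimination of non-significant covariates
#'
#' Iterative model reduction for robust fits: starting from the maximal
#' model, repeatedly refit and remove the unprotected term with the largest
#' p-value above `alpha`, stopping when every unprotected term is
#' significant or when a removal would reduce the adjusted variance-based
#' R-squared (the "maximum explained variance" stopping rule). Protected
#' terms — typically the microbiota measure, the group factor and their
#' interaction — are never candidates, and a main effect participating in a
#' retained interaction is implicitly protected (model hierarchy).
#'
#' @param formula Maximal model formula.
#' @param data Modeling data frame (see [build_feature_table()]).
#' @param protected Character vector of term labels never removed.
#' @param alpha Significance level for retention.
#' @param ... Passed to [fit_huber()].
#' @return A list with elements `fit` (the final [fit_huber()] object),
#'   `formula`, and `trace`: a tibble of `(step, removed, p_at_removal,
#'   r2_adjusted_after)` rows, empty when the maximal model is already the
#'   fixed point.
#' @export
backward_eliminate <- function(formula, data, protected = character(),
                               alpha = 0.05, ...) {
  current <- formula
  fit <- fit_huber(current, data, ...)
  trace <- tibble(step = integer(), removed = character(),
                  p_at_removal = numeric(), r2_adjusted_after = numeric())
  step <- 0L
  repeat {
    labs <- attr(terms(current), "term.labels")
    prot <- union(protected, hierarchy_protected(labs))
    cand <- setdiff(labs, prot)
    if (length(cand) == 0) break

    co <- coefficient_tests(fit)
    pvals <- vapply(cand, function(tm) max_term_p(co, tm, data), numeric(1))
    worst <- cand[which.max(pvals)]
    if (max(pvals) <= alpha) break

    reduced <- drop_term(current, worst)
    fit_red <- fit_huber(reduced, data, ...)
    if (fit_red$r2_adjusted < fit$r2_adjusted) break  # removal loses variance

    step <- step + 1L
    trace <- bind_rows(trace, tibble(
      step = step, removed = worst, p_at_removal = max(pvals),
      r2_adjusted_after = fit_red$r2_adjusted))
    current <- reduced
    fit <- fit_red
  }
  list(fit = fit, formula = current, trace = trace)
}

# main effects inside any interaction term are protected
hierarchy_protected <- function(labs) {
  inter <- labs[grepl(":", labs, fixed = TRUE)]
  unique(c(inter, unlist(strsplit(inter, ":", fixed = TRUE))))
}

# p-value attached to a model term: for a factor expanded into several
# columns, the least favourable (largest) coefficient p
max_term_p <- function(co, term_label, data) {
  hits <- co$term == term_label |
    startsWith(co$term, term_label)
  if (!any(hits)) return(0)
  max(co$p.value[hits], na.rm = TRUE)
}

drop_term <- function(formula, term_label) {
  labs <- setdiff(attr(terms(formula), "term.labels"), term_label)
  response <- as.character(formula)[2]
  if (length(labs) == 0) labs <- "1"
  reformulate(labs, response = response)
}
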