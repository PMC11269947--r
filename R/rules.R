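#' Discretize a continuous variable into interval bins
#'
#' Default binning is equal-width over the observed range with right-open
#' intervals, the topmost bin right-closed so every value is assigned
#' exactly once. Explicit edges may be supplied instead (values outside
#' the edges get `NA`).
#'
#' @param values Numeric vector with at least one finite value.
#' @param n_bins Number of equal-width bins (ignored when `edges` given).
#' @param edges Optional increasing vector of bin edges.
#' @return Tibble `value`, `bin` (label like `"[1.80, 2.31)"`), `lower`,
#'   `upper`; the edge vector is attached as `attr(, "edges")`.
#' @export
#' @examples
#' discretize(c(1.8, 2.5, 3.85), n_bins = 4)
discretize <- function(values, n_bins = 4, edges = NULL) {
  fin <- values[is.finite(values)]
  if (!length(fin)) input_error("need at least one finite value")
  if (is.null(edges)) {
    lo <- min(fin)
    hi <- max(fin)
    if (lo == hi) {
      warn("constant variable: single degenerate bin")
      edges <- c(lo, hi)
    } else {
      assert_scalar_count(n_bins, "n_bins")
      edges <- seq(lo, hi, length.out = n_bins + 1)
    }
  }
  if (is.unsorted(edges, strictly = FALSE) || length(edges) < 2) {
    config_error("edges must be nondecreasing with length >= 2")
  }
  nb <- length(edges) - 1
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  idx[idx < 1 | idx > nb] <- NA_integer_
  lab <- sprintf("[%s, %s%s", format(edges[-length(edges)], trim = TRUE),
                 format(edges[-1], trim = TRUE),
                 c(rep(")", nb - 1), "]"))
  out <- tibble(value = values,
                bin = factor(lab[idx], levels = lab),
                lower = edges[idx],
                upper = edges[idx + 1])
  attr(out, "edges") <- edges
  out
}

#' Mine interval association rules
#'
#' Enumerates rules "antecedent => consequent bin" over a table of binned
#' or categorical variables: antecedents are conjunctions of up to
#' `max_order` single-variable predicates (one value per variable), the
#' consequent any observed bin of the consequent variable. For a rule A =>
#' C over n samples, support = 100 |A and C| / n and confidence =
#' 100 |A and C| / |A|; rules with an empty antecedent match-set or below
#' the thresholds are dropped. Rules are ordered by confidence, then
#' support (both descending), then labels.
#'
#' @param data Tibble whose columns are factors/characters (bin each
#'   continuous variable with [discretize()] first).
#' @param antecedents Character vector of antecedent column names (nonempty).
#' @param consequent Name of the consequent column.
#' @param min_support,min_confidence Thresholds in percent.
#' @param max_order Maximum number of conjuncts in an antecedent.
#' @return A `rule_set` tibble: `antecedent` (label), `consequent`
#'   (label), `n_antecedent`, `n_joint`, `support`, `confidence`, plus the
#'   predicate list-column `antecedent_values`.
#' @export
mine_rules <- function(data, antecedents, consequent,
                       min_support = 0, min_confidence = 0, max_order = 2) {
  if (length(antecedents) < 1) input_error("antecedents must be nonempty")
  if (!all(c(antecedents, consequent) %in% names(data))) {
    input_error("antecedent/consequent columns missing from data")
  }
  n <- nrow(data)
  cols <- lapply(data[c(antecedents, consequent)], as.character)
  cons_vals <- unique(stats::na.omit(cols[[consequent]]))

  rules <- list()
  for (ord in seq_len(min(max_order, length(antecedents)))) {
    combos <- utils::combn(antecedents, ord, simplify = FALSE)
    for (vars in combos) {
      val_sets <- lapply(vars, function(v) unique(stats::na.omit(cols[[v]])))
      grid <- expand.grid(val_sets, stringsAsFactors = FALSE)
      names(grid) <- vars
      for (gi in seq_len(nrow(grid))) {
        match_a <- rep(TRUE, n)
        for (v in vars) {
          match_a <- match_a & !is.na(cols[[v]]) & cols[[v]] == grid[gi, v]
        }
        n_a <- sum(match_a)
        if (n_a == 0) next
        for (cv in cons_vals) {
          n_ac <- sum(match_a & !is.na(cols[[consequent]]) & cols[[consequent]] == cv)
          support <- 100 * n_ac / n
          confidence <- 100 * n_ac / n_a
          if (support < min_support || confidence < min_confidence) next
          pred <- stats::setNames(as.character(grid[gi, vars]), vars)
          rules[[length(rules) + 1]] <- tibble(
            antecedent = paste(sprintf("%s=%s", vars, pred), collapse = " & "),
            consequent = sprintf("%s=%s", consequent, cv),
            n_antecedent = n_a, n_joint = n_ac,
            support = support, confidence = confidence,
            antecedent_values = list(pred),
            consequent_value = cv
          )
        }
      }
    }
  }
  out <- if (length(rules)) dplyr::bind_rows(rules) else {
    tibble(antecedent = character(), consequent = character(),
           n_antecedent = integer(), n_joint = integer(),
           support = double(), confidence = double(),
           antecedent_values = list(), consequent_value = character())
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$confidence),
                        dplyr::desc(.data$support),
                        .data$antecedent, .data$consequent)
  structure(out, class = c("rule_set", class(out)),
            n_samples = n, consequent_variable = consequent)
}

#' Predict a consequent bin from mined rules
#'
#' Applies the mined rules to a new sample's antecedent values and returns
#' the consequent bin of the highest-confidence applicable rule (ties
#' broken by higher support).
#'
#' @param rules A `rule_set` from [mine_rules()].
#' @param newdata Named list or one-row data frame of antecedent values
#'   (bin labels/categories).
#' @return The predicted consequent bin label, or `NA_character_` if no
#'   rule applies.
#' @export
predict_bin <- function(rules, newdata) {
  if (!inherits(rules, "rule_set")) input_error("rules must be a rule_set")
  vals <- if (is.data.frame(newdata)) as.list(newdata[1, ]) else as.list(newdata)
  vals <- lapply(vals, as.character)
  if (nrow(rules) == 0) return(NA_character_)
  applies <- vapply(rules$antecedent_values, function(pred) {
    all(names(pred) %in% names(vals)) &&
      all(mapply(function(v, nm) !is.na(vals[[nm]]) && vals[[nm]] == v,
                 pred, names(pred)))
  }, logical(1))
  if (!any(applies)) return(NA_character_)
  hit <- rules[applies, ]
  hit <- hit[order(-hit$confidence, -hit$support), ]
  hit$consequent_value[1]
}
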