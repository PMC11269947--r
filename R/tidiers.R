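#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn taxon_screen Tidy the screen into a plain tibble.
#' @param x A `taxon_screen` object.
#' @param ... Unused.
#' @method tidy taxon_screen
#' @export
tidy.taxon_screen <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' @describeIn taxon_screen One-row summary: features tested, counts per
#'   significance tier.
#' @method glance taxon_screen
#' @export
glance.taxon_screen <- function(x, ...) {
  tibble(n_taxa = nrow(x),
         n_sig_raw = sum(x$p_raw < 0.05, na.rm = TRUE),
         n_sig_adjusted = sum(x$p_adjusted < 0.05, na.rm = TRUE),
         test = attr(x, "test") %||% NA_character_)
}

#' @describeIn mine_rules Tidy the rule set (labels and scores, no
#'   list-columns).
#' @param x A `rule_set` object.
#' @param ... Unused.
#' @method tidy rule_set
#' @export
tidy.rule_set <- function(x, ...) {
  out <- as_tibble(unclass(x)[names(x)])
  dplyr::select(out, "antecedent", "consequent", "n_antecedent", "n_joint",
                "support", "confidence") |>
    dplyr::mutate(support = round(.data$support, 2),
                  confidence = round(.data$confidence, 2))
}

#' @describeIn mine_rules One-row summary of the rule set.
#' @method glance rule_set
#' @export
glance.rule_set <- function(x, ...) {
  tibble(n_rules = nrow(x),
         n_samples = attr(x, "n_samples"),
         consequent_variable = attr(x, "consequent_variable"))
}

#' @describeIn pca_scores Tidy sample scores.
#' @param x An `mgs_pca` object.
#' @param ... Unused.
#' @method tidy mgs_pca
#' @export
tidy.mgs_pca <- function(x, ...) x$scores

#' @describeIn pca_scores One-row summary of explained variance.
#' @method glance mgs_pca
#' @export
glance.mgs_pca <- function(x, ...) {
  tibble(n_components = length(x$explained_variance),
         var_explained = sum(x$explained_variance),
         var_pc1 = x$explained_variance[1])
}
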