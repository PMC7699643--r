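# Bipartite food-nutrient network: which significant foods carry each
# significant nutrient, and the food-implied (weighted geometric mean)
# nutrient hazard ratio.

#' Normalized food weights for one nutrient
#'
#' `w'_k = a[i, k] / sum_{k' in significant} a[i, k']`: the contribution of
#' each significant source food to the nutrient's total amount over the
#' significant foods.  Scale-invariant in the composition row.
#'
#' @param composition Long-form composition table.
#' @param nutrient A nutrient id.
#' @param significant_foods Food ids in the significant set.
#' @return Named numeric vector summing to 1 over the significant source
#'   foods with positive amounts, or `NULL` when the nutrient has no
#'   positive amount in any significant food.
#' @export
normalized_food_weights <- function(composition, nutrient,
                                    significant_foods) {
  row <- composition %>%
    filter(nutrient_id == nutrient, food_id %in% significant_foods,
      amount > 0)
  if (!nrow(row)) {
    return(NULL)
  }
  w <- setNames(row$amount, row$food_id)
  w / sum(w)
}

#' Expected (food-implied) nutrient hazard ratio
#'
#' The weighted geometric mean of the source-food hazard ratios:
#' `exp(sum_k w'_k * beta_k) = prod_k HR_k ^ w'_k`.
#'
#' @param weights Normalized weights summing to 1.
#' @param food_betas Food effect sizes (log hazard ratios), aligned with
#'   `weights`.
#' @return The expected hazard ratio (a positive scalar).
#' @examples
#' expected_nutrient_hr(c(0.5, 0.5), log(c(0.8, 1.25))) # exactly 1
#' @export
expected_nutrient_hr <- function(weights, food_betas) {
  if (length(weights) != length(food_betas)) {
    abort("weights and food_betas must have the same length")
  }
  if (any(!is.finite(food_betas))) abort("food effect sizes must be finite")
  exp(sum(weights * food_betas))
}

#' Build the bipartite food-nutrient network of significant exposures
#'
#' Restricts the composition table to significant foods and nutrients,
#' normalizes each nutrient's source weights over the significant foods,
#' and attaches node attributes (direction of association, absolute effect
#' size) and edge weights ready for layout or export.  Nutrients whose
#' only sources are non-significant foods are dropped and logged.
#'
#' @param results An `ewas_results` tibble with the `significant` flag
#'   filled (see [add_fdr()]).
#' @param composition Long-form composition table.
#' @param weighting `"per_serving"` (default) uses composition amounts per
#'   serving; `"consumption"` multiplies amounts by mean servings/day of
#'   each food, requiring `mean_servings`.
#' @param mean_servings Named vector of mean servings/day per food id
#'   (only for `weighting = "consumption"`).
#' @return A `food_nutrient_network`: list with `graph` (igraph bipartite
#'   graph), `nodes`, `edges` tibbles, and `dropped` (nutrient ids without
#'   significant sources).
#' @export
build_network <- function(results, composition,
                          weighting = c("per_serving", "consumption"),
                          mean_servings = NULL) {
  weighting <- match.arg(weighting)
  sig <- results %>% filter(significant)
  sig_foods <- sig %>%
    filter(type == "food") %>%
    pull(exposure_id)
  sig_nutrients <- sig %>%
    filter(type == "nutrient") %>%
    pull(exposure_id)
  if (!length(sig_nutrients) || !length(sig_foods)) {
    warn("no significant nutrient-food pairs; empty network")
  }

  comp <- composition
  if (weighting == "consumption") {
    if (is.null(mean_servings)) {
      abort("consumption weighting requires mean_servings")
    }
    comp <- comp %>%
      mutate(amount = amount * unname(mean_servings[food_id]))
  }

  edges <- list()
  dropped <- character(0)
  for (nut in sig_nutrients) {
    w <- normalized_food_weights(comp, nut, sig_foods)
    if (is.null(w)) {
      dropped <- c(dropped, nut)
    } else {
      edges[[nut]] <- tibble(
        nutrient_id = nut, food_id = names(w), weight = unname(w)
      )
    }
  }
  edges <- bind_rows(edges)
  if (!nrow(edges)) {
    edges <- tibble(
      nutrient_id = character(), food_id = character(), weight = numeric()
    )
  }

  used_foods <- unique(edges$food_id)
  used_nutrients <- unique(edges$nutrient_id)
  nodes <- sig %>%
    filter(
      exposure_id %in% c(used_foods, used_nutrients)
    ) %>%
    mutate(
      direction = if_else(hazard_ratio < 1, "negative", "positive"),
      size = abs(effect_size)
    ) %>%
    select(
      name = exposure_id, type, hazard_ratio, effect_size, direction, size
    )

  graph <- if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(
      edges %>% select(from = nutrient_id, to = food_id, weight),
      directed = FALSE,
      vertices = nodes
    )
    igraph::V(g)$bipartite <- igraph::V(g)$type == "food"
    g
  } else {
    igraph::make_empty_graph(directed = FALSE)
  }

  structure(
    list(graph = graph, nodes = nodes, edges = edges, dropped = dropped),
    class = "food_nutrient_network"
  )
}

#' @export
print.food_nutrient_network <- function(x, ...) {
  cat(sprintf(
    "<food_nutrient_network> %d nodes, %d edges (%d nutrient(s) dropped)\n",
    nrow(x$nodes), nrow(x$edges), length(x$dropped)
  ))
  invisible(x)
}

#' Export a food-nutrient network
#'
#' Writes GraphML (for graph tooling / force-directed layout) and a flat
#' edge-list TSV.
#'
#' @param network A `food_nutrient_network`.
#' @param graphml_path,edges_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(network, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    readr::write_tsv(network$edges, edges_path)
  }
  invisible(c(graphml_path, edges_path))
}

#' Compare actual and food-implied nutrient hazard ratios
#'
#' For every nutrient in the network: the actual (fitted) hazard ratio,
#' the expected hazard ratio implied by its significant source foods, and
#' whether the two fall on the same side of 1.
#'
#' @param network A `food_nutrient_network` built from scan results.
#' @return A `nutrient_decomposition` tibble: `nutrient_id`, `actual_hr`,
#'   `expected_hr`, `agree`; the `summary` attribute counts agreements.
#' @export
compare_actual_vs_expected <- function(network) {
  if (!nrow(network$edges)) abort("network is empty")
  food_beta <- network$nodes %>%
    filter(type == "food") %>%
    select(food_id = name, beta = effect_size)
  out <- network$edges %>%
    left_join(food_beta, by = "food_id") %>%
    group_by(nutrient_id) %>%
    summarise(expected_hr = exp(sum(weight * beta)), .groups = "drop") %>%
    left_join(
      network$nodes %>%
        filter(type == "nutrient") %>%
        select(nutrient_id = name, actual_hr = hazard_ratio),
      by = "nutrient_id"
    ) %>%
    mutate(agree = sign(log(actual_hr)) == sign(log(expected_hr))) %>%
    select(nutrient_id, actual_hr, expected_hr, agree)
  structure(
    out,
    summary = c(n_agree = sum(out$agree), n_disagree = sum(!out$agree)),
    class = c("nutrient_decomposition", class(out))
  )
}
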