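# Food-composition table: amount of each nutrient per serving of each food.

#' Generate a synthetic food-composition table
#'
#' Builds a sparse nonnegative nutrient-by-food table in which each nutrient
#' is concentrated in a small set of source foods, so that a nutrient-level
#' association can be traced back to the foods that carry it.  Energy
#' (kcal/day, always the first nutrient) is present in every food so that a
#' total caloric intake can be derived from any diet.
#'
#' @param config A [study_config()].
#' @param sources_per_nutrient Optional integer (or length-2 range) giving
#'   the number of source foods per nutrient.  Default: 2 to 6 source foods
#'   per nutrient (capped at `n_foods`), with energy present in all foods.
#' @return A tibble in long form with columns `nutrient_id`, `food_id`,
#'   `amount` (per serving; kcal for energy, arbitrary composition units
#'   otherwise), carrying a `servings` attribute with per-food serving
#'   descriptors.  Zero entries are omitted.
#' @examples
#' comp <- make_composition_table(study_config(n_foods = 10, n_nutrients = 4))
#' head(comp)
#' @export
make_composition_table <- function(config, sources_per_nutrient = NULL) {
  stopifnot(inherits(config, "study_config"))
  foods <- food_ids(config$n_foods)
  nutrients <- nutrient_ids(config$n_nutrients)
  with_seed(config$seed + 1L, {
    rows <- vector("list", length(nutrients))
    for (i in seq_along(nutrients)) {
      nut <- nutrients[i]
      if (is.null(sources_per_nutrient) && nut == "energy_kcal") {
        src <- seq_along(foods)
        amount <- runif(length(src), 30, 250)
      } else {
        n_src <- if (is.null(sources_per_nutrient)) {
          sample(2:6, 1)
        } else if (length(sources_per_nutrient) == 2) {
          sample(sources_per_nutrient[1]:sources_per_nutrient[2], 1)
        } else {
          sources_per_nutrient
        }
        n_src <- max(1L, min(as.integer(n_src), config$n_foods))
        src <- sample(seq_along(foods), n_src)
        amount <- stats::rlnorm(n_src, meanlog = log(5), sdlog = 0.8)
      }
      rows[[i]] <- tibble(
        nutrient_id = nut, food_id = foods[src], amount = amount
      )
    }
    comp <- bind_rows(rows) %>% arrange(nutrient_id, food_id)
  })
  attr(comp, "servings") <- tibble(
    food_id = foods, serving_unit = "1 standard serving"
  )
  validate_composition(comp, nutrients)
  comp
}

#' Validate a food-composition table
#'
#' Checks nonnegativity and that every nutrient has at least one food
#' source with a positive amount.
#'
#' @param composition Long-form composition tibble
#'   (`nutrient_id`, `food_id`, `amount`).
#' @param nutrients Optional character vector of nutrient ids that must all
#'   be present.
#' @return The table, invisibly; errors otherwise.
#' @export
validate_composition <- function(composition, nutrients = NULL) {
  if (any(composition$amount < 0)) abort("composition amounts must be >= 0")
  have <- composition %>%
    filter(amount > 0) %>%
    distinct(nutrient_id) %>%
    pull(nutrient_id)
  want <- nutrients %||% unique(composition$nutrient_id)
  missing <- setdiff(want, have)
  if (length(missing)) {
    abort(paste0(
      "nutrient without food source: ", paste(missing, collapse = ", ")
    ))
  }
  invisible(composition)
}

#' Composition table as a dense nutrient-by-food matrix
#'
#' @inheritParams validate_composition
#' @param foods Optional food ids fixing the column order.
#' @return Numeric matrix with nutrient rows and food columns.
#' @export
composition_matrix <- function(composition, foods = NULL) {
  foods <- foods %||% sort(unique(composition$food_id))
  nutrients <- unique(composition$nutrient_id)
  m <- matrix(0, length(nutrients), length(foods),
    dimnames = list(nutrients, foods)
  )
  idx <- cbind(
    match(composition$nutrient_id, nutrients),
    match(composition$food_id, foods)
  )
  if (anyNA(idx[, 2])) abort("composition references a food not in `foods`")
  m[idx] <- composition$amount
  m
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
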