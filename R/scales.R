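#' Ordinal clinical outcome scales
#'
#' An `outcome_scale` describes an ordered clinical outcome: its category
#' labels stored from worst to best (1-based indices, higher = better), the
#' cut point above which the outcome counts as "favorable", and the cut for
#' the mortality-style dichotomy (the bottom collapsed category versus the
#' rest). Two built-ins mirror common practice in traumatic brain injury and
#' stroke: the Glasgow Outcome Scale with death and vegetative state merged
#' (`"gos4"`, 4 categories) and the modified Rankin Scale with mRS 5 and
#' death merged (`"mrs6"`, 6 categories).
#'
#' @param name scale name.
#' @param categories character vector of category labels, worst to best.
#' @param favorable_cut integer index: categories `>= favorable_cut` are
#'   favorable. Must satisfy `mortality_cut < favorable_cut <= n_categories`.
#' @param mortality_cut integer index; the "mortality" event is being in
#'   categories `<= mortality_cut`. Defaults to 1 (the bottom collapsed
#'   category versus the rest).
#' @return An object of class `outcome_scale`.
#' @examples
#' sc <- builtin_scale("gos4")
#' sc$n_categories  # 4
#' @export
outcome_scale <- function(name, categories, favorable_cut, mortality_cut = 1L) {
  if (!is.character(categories) || length(categories) < 2L)
    stop("'categories' must be a character vector with at least 2 labels")
  if (anyDuplicated(categories))
    stop("'categories' must be distinct")
  K <- length(categories)
  favorable_cut <- stop_if_not_count(favorable_cut, "favorable_cut")
  mortality_cut <- stop_if_not_count(mortality_cut, "mortality_cut")
  if (mortality_cut >= K)
    stop("'mortality_cut' must be below the number of categories")
  if (favorable_cut <= mortality_cut || favorable_cut > K)
    stop("'favorable_cut' must satisfy mortality_cut < favorable_cut <= n_categories")
  structure(
    list(name = as.character(name)[1L], categories = categories,
         n_categories = K, favorable_cut = favorable_cut,
         mortality_cut = mortality_cut),
    class = "outcome_scale")
}

#' @export
print.outcome_scale <- function(x, ...) {
  cat(sprintf("Outcome scale '%s' (%d categories, worst to best):\n",
              x$name, x$n_categories))
  marks <- rep("", x$n_categories)
  marks[x$favorable_cut] <- " <- favorable from here up"
  marks[x$mortality_cut] <- paste0(marks[x$mortality_cut],
                                   " <- mortality-style event at or below")
  cat(paste0(sprintf("  [%d] %s", seq_len(x$n_categories), x$categories),
             marks, collapse = "\n"), "\n")
  invisible(x)
}

# Raw (uncollapsed) label sets used to build the two built-in scales.
gos5_labels <- function() {
  c("death", "vegetative state", "severe disability",
    "moderate disability", "good recovery")
}
mrs7_labels <- function() {
  c("mRS 6 (death)", "mRS 5", "mRS 4", "mRS 3", "mRS 2", "mRS 1", "mRS 0")
}

#' Collapse the two worst categories of an ordinal scale
#'
#' Merges the two worst (adjacent, bottom) categories of a raw scale into a
#' single category, the usual ethically motivated collapse of death with the
#' worst disability state (death + vegetative state for the GOS; death +
#' mRS 5 for the mRS). Category order is preserved and the number of
#' categories drops by one.
#'
#' @param raw_categories character vector of raw labels, worst to best
#'   (or an `outcome_scale`, whose labels are used).
#' @param merge_worst length-2 character vector naming the two categories to
#'   merge; they must be exactly the two worst categories, in order.
#' @param name name for the collapsed scale.
#' @param favorable_cut favorable cut index on the *collapsed* scale.
#' @return An `outcome_scale` with one fewer category.
#' @export
collapse_scale <- function(raw_categories, merge_worst, name = "collapsed",
                           favorable_cut = NULL) {
  if (inherits(raw_categories, "outcome_scale"))
    raw_categories <- raw_categories$categories
  if (!is.character(raw_categories) || length(raw_categories) < 3L)
    stop("collapsing requires a raw scale with at least 3 categories")
  if (length(merge_worst) != 2L ||
      !identical(as.character(merge_worst), raw_categories[1:2]))
    stop("'merge_worst' must be exactly the two worst (first) categories, in order")
  merged <- paste(merge_worst, collapse = " / ")
  categories <- c(merged, raw_categories[-(1:2)])
  if (is.null(favorable_cut)) favorable_cut <- length(categories)
  outcome_scale(name, categories, favorable_cut = favorable_cut,
                mortality_cut = 1L)
}

#' Built-in outcome scales
#'
#' @param name `"gos4"` (collapsed 5-point Glasgow Outcome Scale) or
#'   `"mrs6"` (collapsed 7-point modified Rankin Scale).
#' @return An `outcome_scale`.
#' @details `"gos4"` merges death with vegetative state; favorable outcome is
#'   moderate disability or good recovery. `"mrs6"` merges death (mRS 6) with
#'   mRS 5; favorable outcome is mRS 0-2. In both, the mortality-style
#'   dichotomy is the bottom collapsed category versus the rest.
#' @export
builtin_scale <- function(name = c("gos4", "mrs6")) {
  name <- match.arg(name)
  switch(name,
    gos4 = collapse_scale(gos5_labels(), gos5_labels()[1:2],
                          name = "gos4", favorable_cut = 3L),
    mrs6 = collapse_scale(mrs7_labels(), mrs7_labels()[1:2],
                          name = "mrs6", favorable_cut = 4L))
}

#' Dichotomize ordinal outcomes
#'
#' Collapses ordinal category indices to a binary outcome at one of the
#' scale's two cut points. Under the `"favorable"` cut the result is 1 when
#' the category index is at or above `favorable_cut` (good recovery /
#' moderate disability; mRS 0-2). Under the `"mortality"` cut the result is
#' 1 when the patient is *above* the bottom collapsed category, i.e. the
#' event (death or worst disability state) is coded 0 so that higher remains
#' better in both codings.
#'
#' @param outcomes integer vector of category indices (1 = worst).
#' @param scale an `outcome_scale`.
#' @param cut `"favorable"` or `"mortality"`.
#' @return Integer 0/1 vector.
#' @export
dichotomize <- function(outcomes, scale, cut = c("favorable", "mortality")) {
  cut <- match.arg(cut)
  stopifnot(inherits(scale, "outcome_scale"))
  outcomes <- as.integer(outcomes)
  if (length(outcomes) && (anyNA(outcomes) || min(outcomes) < 1L ||
                           max(outcomes) > scale$n_categories))
    stop(sprintf("outcome indices must be in 1..%d", scale$n_categories))
  if (cut == "favorable") as.integer(outcomes >= scale$favorable_cut)
  else as.integer(outcomes > scale$mortality_cut)
}
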