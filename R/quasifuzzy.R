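# Quasi-fuzzy transform: triangular fuzzification, exhaustive rule firing
# with the product t-norm, and normalisation into the interim output vector.

FUZZY_LABELS <- c("low", "medium", "high")

#' Triangular fuzzy partition of one variable
#'
#' Three linguistic labels (low / medium / high) over a variable's data
#' space, defined by the lower bound `l`, the medium peak `m` and the upper
#' bound `h` (`l < m < h`). With the symmetric default `m = (l + h) / 2` the
#' three memberships form a partition of unity for every input, including
#' values outside `[l, h]` (the extreme labels saturate at 1 there).
#'
#' @param variable One of `"tmin","tmax","ws","rh","sr"`.
#' @param l,m,h Break points in the variable's units, `l < m < h`.
#' @return An object of class `fuzzy_partition`.
#' @export
fuzzy_partition <- function(variable, l, m, h) {
  variable <- match.arg(variable, WEATHER_VARS)
  stopifnot(is.numeric(l), is.numeric(m), is.numeric(h))
  if (!(l < m && m < h)) stop("require l < m < h", call. = FALSE)
  structure(list(variable = variable, l = as.numeric(l), m = as.numeric(m),
                 h = as.numeric(h)),
            class = "fuzzy_partition")
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf("<fuzzy_partition> %s: l=%.4g m=%.4g h=%.4g\n",
              x$variable, x$l, x$m, x$h))
  invisible(x)
}

#' Fit a partition from training data
#'
#' `l` and `h` are the observed minimum and maximum of the variable in the
#' series; `m` is the midpoint `(l + h) / 2`. Partitions must be fit on the
#' training split only, so the data space never leaks test information;
#' test-time values outside `[l, h]` are handled by clamped memberships.
#'
#' @param series A [weather_series()].
#' @param variable Variable name.
#' @return A [fuzzy_partition()].
#' @export
fit_partition <- function(series, variable) {
  variable <- match.arg(variable, WEATHER_VARS)
  x <- series[[variable]]
  if (is.null(x)) stop("variable ", variable, " absent from series",
                       call. = FALSE)
  x <- x[!is.na(x)]
  l <- min(x); h <- max(x)
  if (l == h) stop("variable ", variable, " is constant; cannot partition",
                   call. = FALSE)
  fuzzy_partition(variable, l, (l + h) / 2, h)
}

#' Fit partitions for several variables at once
#' @param series A [weather_series()].
#' @param variables Character vector; default all available.
#' @return Named list of [fuzzy_partition()] objects.
#' @export
fit_partitions <- function(series, variables = available_variables(series)) {
  out <- lapply(variables, fit_partition, series = series)
  names(out) <- variables
  out
}

#' Membership degrees of values in a partition
#'
#' Triangular memberships: low falls linearly from 1 at `l` to 0 at `m`;
#' medium rises from 0 at `l` to 1 at `m` and falls to 0 at `h`; high rises
#' from 0 at `m` to 1 at `h`. Values below `l` (above `h`) are clamped to
#' the low (high) vertex, so out-of-range inputs always keep one label fully
#' alive — the design answer to the out-of-range failure mode of
#' grid-partition neuro-fuzzy systems.
#'
#' @param x Numeric vector of values.
#' @param p A [fuzzy_partition()].
#' @return Matrix `length(x)` x 3 with columns `low`, `medium`, `high`;
#'   rows sum to 1.
#' @export
membership_degrees <- function(x, p) {
  stopifnot(inherits(p, "fuzzy_partition"))
  lo <- ifelse(x <= p$l, 1,
               ifelse(x >= p$m, 0, (p$m - x) / (p$m - p$l)))
  hi <- ifelse(x <= p$m, 0,
               ifelse(x >= p$h, 1, (x - p$m) / (p$h - p$m)))
  me <- ifelse(x <= p$l | x >= p$h, 0,
               ifelse(x <= p$m, (x - p$l) / (p$m - p$l),
                      (p$h - x) / (p$h - p$m)))
  cbind(low = lo, medium = me, high = hi)
}

#' The eight standard input combinations
#'
#' Every combination contains the base temperature pair (tmin, tmax), which
#' is measured by a single instrument and assumed always available; the
#' other three variables appear in all subsets: C1 = base, C2 = +ws,
#' C3 = +rh, C4 = +sr, C5 = +ws+rh, C6 = +ws+sr, C7 = +rh+sr, C8 = all five.
#' Variable order within each combination is fixed as
#' (tmin, tmax, ws, rh, sr) restricted to members.
#'
#' @return Named list `C1`..`C8` of character vectors.
#' @export
standard_combinations <- function() {
  list(
    C1 = c("tmin", "tmax"),
    C2 = c("tmin", "tmax", "ws"),
    C3 = c("tmin", "tmax", "rh"),
    C4 = c("tmin", "tmax", "sr"),
    C5 = c("tmin", "tmax", "ws", "rh"),
    C6 = c("tmin", "tmax", "ws", "sr"),
    C7 = c("tmin", "tmax", "rh", "sr"),
    C8 = c("tmin", "tmax", "ws", "rh", "sr")
  )
}

#' Rule-group sizes
#'
#' `3^k` rules per k-variable combination: 9, 27, 27, 27, 81, 81, 81, 243
#' for C1..C8 (576 in total across the eight groups).
#'
#' @return Named integer vector.
#' @export
rule_group_sizes <- function() {
  vapply(standard_combinations(), function(v) as.integer(3^length(v)),
         integer(1))
}

resolve_combination <- function(combination) {
  combos <- standard_combinations()
  if (is.character(combination) && length(combination) == 1L &&
      combination %in% names(combos)) {
    return(list(id = combination, variables = combos[[combination]]))
  }
  if (is.character(combination) && all(combination %in% WEATHER_VARS)) {
    vars <- intersect(WEATHER_VARS, combination)
    id <- names(combos)[vapply(combos, identical, logical(1), y = vars)]
    if (!length(id)) stop("combination must contain the base pair tmin, tmax",
                          call. = FALSE)
    return(list(id = id, variables = vars))
  }
  stop("unknown combination: ", paste(combination, collapse = ","),
       call. = FALSE)
}

#' Enumerate the exhaustive rule group of a combination
#'
#' The complete Cartesian product of the three labels over the combination's
#' variables, ordered lexicographically with variable order
#' (tmin, tmax, ws, rh, sr) most-significant-first and label order
#' low < medium < high: the first rule is all-low, the last all-high.
#'
#' @param combination A combination id (`"C1"`..`"C8"`) or a character
#'   vector of variable names containing the base pair.
#' @return An object of class `rule_group`: list with `id`, `variables`,
#'   `rules` (a `3^k` x k integer matrix of label indices 1..3) and `size`.
#' @export
enumerate_rule_group <- function(combination) {
  cc <- resolve_combination(combination)
  k <- length(cc$variables)
  # expand.grid varies the first factor fastest; feed variables in reverse so
  # the first variable becomes the most significant digit, then restore order
  grid <- expand.grid(rev(replicate(k, 1:3, simplify = FALSE)))
  rules <- as.matrix(grid[, rev(seq_len(k)), drop = FALSE])
  dimnames(rules) <- list(NULL, cc$variables)
  structure(list(id = cc$id, variables = cc$variables, rules = rules,
                 size = nrow(rules)),
            class = "rule_group")
}

#' @export
print.rule_group <- function(x, ...) {
  cat(sprintf("<rule_group> %s over (%s): %d rules\n", x$id,
              paste(x$variables, collapse = ", "), x$size))
  invisible(x)
}

#' Rule labels as text
#' @param group A [enumerate_rule_group()] result.
#' @return Character matrix of `low`/`medium`/`high` labels.
#' @export
rule_labels <- function(group) {
  stopifnot(inherits(group, "rule_group"))
  out <- matrix(FUZZY_LABELS[group$rules], nrow = group$size)
  colnames(out) <- group$variables
  out
}

#' Fire every rule of a group with the product t-norm
#'
#' For each record and each rule, the firing strength is the product over
#' the rule's variables of the membership degree of the rule's label at the
#' record's value. All rules are always fired; with the symmetric default
#' partitions the strengths of a group sum to 1 per record (a product of
#' partitions of unity).
#'
#' @param records A [weather_series()] or data frame carrying the group's
#'   variables.
#' @param group A `rule_group`.
#' @param partitions Named list of [fuzzy_partition()], one per variable of
#'   the group.
#' @return Matrix `nrow(records)` x `group$size` of firing strengths in
#'   [0, 1].
#' @export
fire_rule_group <- function(records, group, partitions) {
  stopifnot(inherits(group, "rule_group"))
  missing_vars <- setdiff(group$variables, names(records))
  if (length(missing_vars)) {
    stop("record lacks variable(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  missing_parts <- setdiff(group$variables, names(partitions))
  if (length(missing_parts)) {
    stop("no partition for variable(s): ",
         paste(missing_parts, collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  firing <- matrix(1, nrow = n, ncol = group$size)
  for (v in group$variables) {
    mu <- membership_degrees(records[[v]], partitions[[v]])  # n x 3
    firing <- firing * mu[, group$rules[, v], drop = FALSE]
  }
  firing
}

#' Normalise firing strengths into an interim vector
#'
#' Each rule's contribution is made proportionate within its group:
#' `I_i = P_i / sum(P)` per record. The normalised vector is the feature
#' vector handed to the neural head (the quasi-fuzzy replacement for
#' defuzzification).
#'
#' @param firing Matrix of firing strengths (records x rules), or a vector
#'   for a single record.
#' @return Matrix of the same shape; rows sum to 1.
#' @export
normalize_firings <- function(firing) {
  if (is.null(dim(firing))) firing <- matrix(firing, nrow = 1)
  totals <- rowSums(firing)
  dead <- which(totals == 0)
  if (length(dead)) {
    stop("all-zero firing at record(s) ",
         paste(utils::head(dead, 5L), collapse = ", "), call. = FALSE)
  }
  firing / totals
}

#' Quasi-fuzzy transform: records to interim output vectors
#'
#' Composition of [fire_rule_group()] and [normalize_firings()] for the rule
#' group matching the requested combination (the rule-group selector).
#'
#' @param records A [weather_series()] or data frame.
#' @param combination Combination id or variable vector.
#' @param partitions Named list of [fuzzy_partition()].
#' @return Matrix `nrow(records)` x `3^k`; rows sum to 1.
#' @export
interim_vectors <- function(records, combination, partitions) {
  group <- enumerate_rule_group(combination)
  normalize_firings(fire_rule_group(records, group, partitions))
}
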