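#' Construct an additive value-set table
#'
#' A value-set table holds the per-item, per-level utility decrements of an
#' additive multi-attribute scoring function (the form used by EQ-5D-5L
#' tariffs): the utility of a health state is the full-health anchor minus
#' the sum of the decrements selected by the respondent's item levels.
#'
#' @param decrements data frame with columns `item`, `level` (1-5) and
#'   `decrement` (utility units, 0 at level 1), covering five levels for
#'   every item.
#' @param instrument label for the instrument the table scores.
#' @param anchor utility of the all-level-1 (full health) state.
#' @param minimum,maximum declared theoretical score range. Defaults are
#'   derived from the table (anchor minus worst decrements, and the anchor).
#' @return An object of class `value_set_table`.
#' @export
value_set_table <- function(decrements, instrument = "EQ-5D-5L", anchor = 1,
                            minimum = NULL, maximum = NULL) {
  need <- c("item", "level", "decrement")
  if (!is.data.frame(decrements) || !all(need %in% names(decrements)))
    stop("`decrements` must be a data frame with columns item, level, decrement",
         call. = FALSE)
  decrements$item <- as.character(decrements$item)
  decrements$level <- as.integer(decrements$level)
  decrements$decrement <- as.numeric(decrements$decrement)
  items <- unique(decrements$item)
  for (it in items) {
    sub <- decrements[decrements$item == it, ]
    if (!setequal(sub$level, 1:5))
      stop(sprintf("item '%s' must have decrements for levels 1..5", it),
           call. = FALSE)
    if (abs(sub$decrement[sub$level == 1]) > 1e-12)
      stop(sprintf("item '%s': level-1 decrement must be 0", it), call. = FALSE)
    if (any(!is.finite(sub$decrement)))
      stop(sprintf("item '%s': non-finite decrement", it), call. = FALSE)
  }
  worst <- sum(vapply(items, function(it)
    max(decrements$decrement[decrements$item == it]), numeric(1)))
  if (is.null(minimum)) minimum <- anchor - worst
  if (is.null(maximum)) maximum <- anchor
  if (minimum > anchor - worst + 1e-9 || maximum < anchor - 1e-9)
    stop("declared [minimum, maximum] does not cover the achievable scores",
         call. = FALSE)
  structure(list(instrument = instrument, items = items,
                 decrements = decrements[order(decrements$item, decrements$level), ],
                 anchor = anchor, minimum = minimum, maximum = maximum),
            class = "value_set_table")
}

#' @export
print.value_set_table <- function(x, ...) {
  cat(sprintf("<value_set_table> %s: %d items, anchor %.3f, range [%.3f, %.3f]\n",
              x$instrument, length(x$items), x$anchor, x$minimum, x$maximum))
  invisible(x)
}

#' The packaged U.S. EQ-5D-5L value set
#'
#' Loads the packaged U.S. time trade-off tariff for the EQ-5D-5L
#' (theoretical range -0.573 to 1).
#' @return A [value_set_table].
#' @export
eq5d5l_us <- function() {
  read_value_set(system.file("extdata", "eq5d5l_us_value_set.csv",
                             package = "prefcross", mustWork = TRUE))
}

# Parse leading "# key=value" comment lines of a config file
.read_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  list(meta = meta, body = lines[!grepl("^#", lines)])
}

.meta_num <- function(meta, key, path) {
  v <- suppressWarnings(as.numeric(meta[[key]]))
  if (length(v) != 1 || is.na(v))
    stop(sprintf("configuration error in '%s': missing or non-numeric field '%s'",
                 path, key), call. = FALSE)
  v
}

#' Read a scoring specification from a delimited text file
#'
#' Value-set files carry `# key=value` metadata lines followed by a CSV
#' body. Additive tables have columns `item, level, decrement` and metadata
#' `anchor`, `minimum`, `maximum`; multiplicative (MAUT) specifications have
#' columns `domain, score, disutility` and metadata `util_best`,
#' `util_worst` plus one `weight.<domain>` entry per domain.
#'
#' @param path path to the file.
#' @return A [value_set_table] or [maut_spec], depending on the file body.
#' @export
read_value_set <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' not found", path), call. = FALSE)
  parsed <- .read_meta(path)
  body <- parsed$body
  if (!length(body)) stop(sprintf("configuration error in '%s': empty body", path),
                          call. = FALSE)
  header <- strsplit(body[[1]], ",")[[1]]
  df <- tryCatch(
    read.csv(text = paste(body, collapse = "\n"), stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("configuration error in '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  if (all(c("item", "level", "decrement") %in% header)) {
    value_set_table(df,
                    instrument = parsed$meta[["instrument"]] %||% "unknown",
                    anchor = .meta_num(parsed$meta, "anchor", path),
                    minimum = .meta_num(parsed$meta, "minimum", path),
                    maximum = .meta_num(parsed$meta, "maximum", path))
  } else if (all(c("domain", "score", "disutility") %in% header)) {
    wkeys <- grep("^weight\\.", names(parsed$meta), value = TRUE)
    if (!length(wkeys))
      stop(sprintf("configuration error in '%s': no 'weight.<domain>' fields", path),
           call. = FALSE)
    w <- vapply(wkeys, function(k) .meta_num(parsed$meta, k, path), numeric(1))
    names(w) <- sub("^weight\\.", "", wkeys)
    maut_spec(knots = df, weights = w,
              util_best = .meta_num(parsed$meta, "util_best", path),
              util_worst = .meta_num(parsed$meta, "util_worst", path),
              instrument = parsed$meta[["instrument"]] %||% "unknown")
  } else {
    stop(sprintf("configuration error in '%s': unrecognized header '%s'",
                 path, body[[1]]), call. = FALSE)
  }
}

#' Write a scoring specification back to delimited text
#'
#' Inverse of [read_value_set()]; a written file reads back to an identical
#' specification.
#' @param x a [value_set_table] or [maut_spec].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_value_set <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "value_set_table")) {
    writeLines(c(sprintf("# instrument=%s", x$instrument),
                 sprintf("# anchor=%.15g", x$anchor),
                 sprintf("# minimum=%.15g", x$minimum),
                 sprintf("# maximum=%.15g", x$maximum)), con)
    write.csv(x$decrements, con, row.names = FALSE, quote = FALSE)
  } else if (inherits(x, "maut_spec")) {
    writeLines(c(sprintf("# instrument=%s", x$instrument),
                 sprintf("# util_best=%.15g", x$util_best),
                 sprintf("# util_worst=%.15g", x$util_worst),
                 sprintf("# weight.%s=%.15g", names(x$weights), x$weights)), con)
    write.csv(x$knots, con, row.names = FALSE, quote = FALSE)
  } else stop("`x` must be a value_set_table or maut_spec", call. = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a multiplicative multi-attribute (MAUT) scoring specification
#'
#' The PROPr-style scoring function: each domain score maps to a disutility
#' in \[0, 1\] through a tabulated monotone curve (linear interpolation
#' between knots), the domain disutilities are combined multiplicatively
#' with single-attribute corner weights, and the aggregate disutility is
#' rescaled affinely so that the all-best profile attains `util_best` and
#' the all-worst profile `util_worst`.
#'
#' The multiplicative scale constant `C` solves
#' `1 + C = prod(1 + C * w_j)`; it is found at construction time and the
#' aggregate disutility is `(prod(1 + C * w_j * du_j) - 1) / C`, which is 0
#' at all-best and 1 at all-worst by construction. When the weights sum to
#' 1 the additive limit (`C -> 0`) is used.
#'
#' @param knots data frame with columns `domain`, `score`, `disutility`;
#'   per domain the curve must be monotone in `score` and span disutility
#'   0 to 1.
#' @param weights named positive vector of single-attribute corner weights,
#'   one per domain in `knots`.
#' @param util_best,util_worst utilities of the all-best / all-worst
#'   profiles (the declared maximum and minimum).
#' @param instrument label.
#' @return An object of class `maut_spec`.
#' @export
maut_spec <- function(knots, weights, util_best, util_worst,
                      instrument = "PROPr") {
  need <- c("domain", "score", "disutility")
  if (!is.data.frame(knots) || !all(need %in% names(knots)))
    stop("`knots` must be a data frame with columns domain, score, disutility",
         call. = FALSE)
  knots$domain <- as.character(knots$domain)
  domains <- unique(knots$domain)
  if (is.null(names(weights)) || !setequal(names(weights), domains))
    stop("`weights` must be named and match the domains in `knots`", call. = FALSE)
  if (any(weights <= 0)) stop("all weights must be positive", call. = FALSE)
  if (util_worst >= util_best) stop("util_worst must be below util_best", call. = FALSE)
  curves <- list()
  for (d in domains) {
    sub <- knots[knots$domain == d, ]
    sub <- sub[order(sub$score), ]
    if (nrow(sub) < 2 || any(!is.finite(sub$score)) || any(!is.finite(sub$disutility)))
      stop(sprintf("domain '%s': need >= 2 finite knots", d), call. = FALSE)
    dd <- diff(sub$disutility)
    if (!(all(dd >= -1e-12) || all(dd <= 1e-12)))
      stop(sprintf("domain '%s': disutility curve must be monotone in score", d),
           call. = FALSE)
    if (abs(min(sub$disutility)) > 1e-9 || abs(max(sub$disutility) - 1) > 1e-9)
      stop(sprintf("domain '%s': disutility must span 0 to 1", d), call. = FALSE)
    curves[[d]] <- sub
  }
  wsum <- sum(weights)
  if (abs(wsum - 1) < 1e-10) {
    C <- 0
  } else {
    f <- function(C) prod(1 + C * weights) - (1 + C)
    # weights summing above 1 give C in (-1, 0); below 1, C > 0
    C <- if (wsum > 1) uniroot(f, c(-1 + 1e-12, -1e-12), tol = 1e-14)$root
         else uniroot(f, c(1e-12, 1e6), tol = 1e-12)$root
  }
  structure(list(instrument = instrument, domains = domains, knots = knots,
                 curves = curves, weights = weights[domains], scale_c = C,
                 util_best = util_best, util_worst = util_worst,
                 minimum = util_worst, maximum = util_best),
            class = "maut_spec")
}

#' @export
print.maut_spec <- function(x, ...) {
  cat(sprintf("<maut_spec> %s: %d domains, multiplicative C = %.4f, range [%.3f, %.3f]\n",
              x$instrument, length(x$domains), x$scale_c, x$minimum, x$maximum))
  invisible(x)
}

#' The packaged PROPr-style MAUT specification (synthetic curves)
#'
#' Loads the packaged multiplicative specification on the published PROPr
#' score range (-0.022 to 0.954). The per-domain disutility curves are
#' synthetic stand-ins (smooth monotone tabulations), not the published
#' estimates; scores from this specification reproduce the instrument's
#' range, anchoring and functional form but not the published per-state
#' values.
#' @return A [maut_spec].
#' @export
propr_us_synthetic <- function() {
  read_value_set(system.file("extdata", "propr_maut_synthetic.csv",
                             package = "prefcross", mustWork = TRUE))
}

.as_state_matrix <- function(state, cols, what) {
  if (is.data.frame(state)) state <- as.matrix(state[, cols, drop = FALSE])
  else if (is.numeric(state) && is.null(dim(state))) {
    if (length(state) != length(cols))
      stop(sprintf("`%s` must have %d values (%s)", what, length(cols),
                   paste(cols, collapse = ", ")), call. = FALSE)
    state <- matrix(state, nrow = 1, dimnames = list(NULL, cols))
  } else if (is.matrix(state)) {
    if (!is.null(colnames(state))) state <- state[, cols, drop = FALSE]
  } else stop(sprintf("`%s` must be a numeric vector, matrix or data frame", what),
              call. = FALSE)
  if (ncol(state) != length(cols))
    stop(sprintf("`%s` must have %d columns", what, length(cols)), call. = FALSE)
  colnames(state) <- cols
  state
}

#' Score EQ-5D-5L health states
#'
#' Computes the utility of one or more five-item health states as the
#' full-health anchor minus the sum of the value-set decrements selected by
#' the item levels.
#'
#' @param state a length-5 numeric vector of item levels (1-5) in the order
#'   mobility, self-care, usual activities, pain/discomfort,
#'   anxiety/depression; or an n-by-5 matrix / data frame (columns matched
#'   by the table's item names when present).
#' @param table a [value_set_table]; defaults to the U.S. tariff.
#' @return Numeric vector of utilities, one per state.
#' @examples
#' score_eq5d(c(1, 1, 1, 1, 1))           # full health: 1
#' score_eq5d(c(5, 5, 5, 5, 5))           # worst state: -0.573 (U.S. tariff)
#' @export
score_eq5d <- function(state, table = eq5d5l_us()) {
  if (!inherits(table, "value_set_table"))
    stop("`table` must be a value_set_table", call. = FALSE)
  m <- .as_state_matrix(state, table$items, "state")
  if (any(is.na(m)) || any(m != round(m)) || any(m < 1) || any(m > 5))
    stop("validation error: every item level must be an integer in 1..5",
         call. = FALSE)
  dec <- matrix(NA_real_, 5, length(table$items),
                dimnames = list(NULL, table$items))
  for (it in table$items) {
    sub <- table$decrements[table$decrements$item == it, ]
    dec[sub$level, it] <- sub$decrement
  }
  if (any(is.na(dec))) stop("configuration error: missing table entry", call. = FALSE)
  totals <- rep(0, nrow(m))
  for (it in table$items) totals <- totals + dec[m[, it], it]
  u <- table$anchor - totals
  unname(pmin(pmax(u, table$minimum), table$maximum))
}

#' Score PROPr-style profiles with a multiplicative MAUT specification
#'
#' Maps each domain score to a disutility through the spec's tabulated
#' curve (linear interpolation, clamped at the curve ends), combines the
#' domain disutilities multiplicatively and rescales affinely onto the
#' declared utility range.
#'
#' @param profile a length-7 numeric vector of domain scores in the spec's
#'   domain order, or an n-by-7 matrix / data frame with domain-named
#'   columns.
#' @param spec a [maut_spec]; defaults to the packaged synthetic
#'   specification.
#' @return Numeric vector of utilities.
#' @export
score_propr <- function(profile, spec = propr_us_synthetic()) {
  if (!inherits(spec, "maut_spec")) stop("`spec` must be a maut_spec", call. = FALSE)
  m <- .as_state_matrix(profile, spec$domains, "profile")
  if (any(!is.finite(m)))
    stop("validation error: all domain scores must be present and finite",
         call. = FALSE)
  C <- spec$scale_c
  n <- nrow(m)
  du <- matrix(0, n, length(spec$domains), dimnames = list(NULL, spec$domains))
  for (d in spec$domains) {
    cv <- spec$curves[[d]]
    du[, d] <- approx(cv$score, cv$disutility, xout = m[, d], rule = 2)$y
  }
  if (C == 0) {
    agg <- as.vector(du %*% spec$weights)   # additive limit
  } else {
    prodterm <- rep(1, n)
    for (d in spec$domains) prodterm <- prodterm * (1 + C * spec$weights[[d]] * du[, d])
    agg <- (prodterm - 1) / C
  }
  u <- spec$util_best - (spec$util_best - spec$util_worst) * agg
  unname(pmin(pmax(u, spec$minimum), spec$maximum))
}

#' Append utility columns to a person-level table
#'
#' Scores the EQ-5D-5L item columns (`eq5d_mo`, `eq5d_sc`, `eq5d_ua`,
#' `eq5d_pd`, `eq5d_ad`) and the seven PROMIS domain columns (named as in
#' the MAUT spec), appending `eq5d_utility` and `propr_utility`. Either
#' instrument's columns may be absent, in which case that utility is
#' skipped.
#'
#' @param data person-level data frame.
#' @param table a [value_set_table] for the EQ-5D-5L.
#' @param spec a [maut_spec] for the PROPr.
#' @return `data` with utility columns appended.
#' @export
score_utilities <- function(data, table = eq5d5l_us(), spec = propr_us_synthetic()) {
  eq_cols <- c("eq5d_mo", "eq5d_sc", "eq5d_ua", "eq5d_pd", "eq5d_ad")
  if (all(eq_cols %in% names(data))) {
    m <- as.matrix(data[, eq_cols])
    colnames(m) <- table$items
    data$eq5d_utility <- score_eq5d(m, table)
  }
  if (all(spec$domains %in% names(data)))
    data$propr_utility <- score_propr(data[, spec$domains], spec)
  if (!("eq5d_utility" %in% names(data)) && !("propr_utility" %in% names(data)))
    stop("no scorable columns found (EQ-5D-5L items or PROMIS domains)",
         call. = FALSE)
  data
}
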