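## COSMI: combinatorially optimized coding by sparse, multilobe inhibitory
## neurons. A code assigns each inhibitory unit a receptive field (RF) -- the
## set of channels that drive it -- and, under the donut rule, the unit
## projects inhibition to exactly the channels outside its RF. A code is
## usable for selection iff for every ordered channel pair (i, j), i != j,
## some unit is driven by i and projects to j (pairwise coverage), so that a
## stimulus at i delivers competitive inhibition at j.

#' Construct a combinatorial inhibitory code
#'
#' @param rfs list of integer vectors; `rfs[[u]]` is the set of channels in
#'   unit `u`'s receptive field (its "lobes"). Each RF must be a non-empty
#'   strict subset of `1:n_channels`.
#' @param n_channels number of channels `L`.
#' @return an object of class `cosmi_code`.
#' @examples
#' copy_paste_code(3)                  # one singleton RF per channel
#' cosmi_code(list(c(1, 2), c(2, 3), c(3, 1)), n_channels = 3)
#' @export
cosmi_code <- function(rfs, n_channels) {
  stopifnot(is.list(rfs), length(rfs) >= 1L, n_channels >= 1L)
  n_channels <- as.integer(n_channels)
  rfs <- lapply(rfs, function(rf) sort(unique(as.integer(rf))))
  for (u in seq_along(rfs)) {
    rf <- rfs[[u]]
    if (length(rf) == 0L) {
      stop("RF of unit ", u, " is empty")
    }
    if (any(rf < 1L | rf > n_channels)) {
      stop("RF of unit ", u, " references channels outside 1..", n_channels)
    }
    if (length(rf) == n_channels) {
      stop("RF of unit ", u, " covers every channel; RFs must be strict subsets")
    }
  }
  structure(list(rfs = rfs, n_channels = n_channels), class = "cosmi_code")
}

#' Copy-and-paste baseline code: one singleton-RF unit per channel
#'
#' The brute-force layout in which the pairwise selection module is replicated
#' for every channel: unit `i` is driven by channel `i` alone and (under the
#' donut rule) inhibits all other channels.
#'
#' @param n_channels number of channels `L >= 2`.
#' @return a `cosmi_code`.
#' @export
copy_paste_code <- function(n_channels) {
  stopifnot(n_channels >= 2L)
  cosmi_code(as.list(seq_len(n_channels)), n_channels)
}

#' Level-k antichain code (multilobe receptive fields)
#'
#' Builds a covered code with `n_units` units by assigning each channel a
#' distinct k-subset of units as its "incidence" (the units it drives), with
#' the smallest k such that `choose(n_units, k) >= n_channels`. For
#' `n_channels = 6, n_units = 4` this reproduces the classic 4-unit multilobe
#' arrangement in which each unit has a 3-lobe RF and every ordered channel
#' pair is covered.
#'
#' @param n_channels number of channels `L >= 2`.
#' @param n_units number of inhibitory units.
#' @return a `cosmi_code`.
#' @export
antichain_code <- function(n_channels, n_units) {
  stopifnot(n_channels >= 2L, n_units >= 2L)
  k <- NA_integer_
  for (kk in seq_len(n_units - 1L)) {
    if (choose(n_units, kk) >= n_channels) {
      k <- kk
      break
    }
  }
  if (is.na(k)) {
    stop("no antichain of ", n_channels, " subsets exists for ", n_units,
         " units (Sperner bound exceeded)")
  }
  inc <- utils::combn(n_units, k)[, seq_len(n_channels), drop = FALSE]
  rfs <- lapply(seq_len(n_units), function(u) {
    which(apply(inc == u, 2, any))
  })
  cosmi_code(rfs, n_channels)
}

#' Check pairwise coverage of a combinatorial code
#'
#' A code supports selection among all viable pairs iff for every ordered
#' channel pair (i, j), i != j, some unit has i in its RF and j outside it.
#'
#' @param code a `cosmi_code`.
#' @return list with `ok` (logical) and `uncovered` (two-column integer matrix
#'   of uncovered ordered pairs; zero rows when covered).
#' @export
coverage_ok <- function(code) {
  stopifnot(inherits(code, "cosmi_code"))
  L <- code$n_channels
  member <- rf_membership(code)   # units x channels logical
  uncovered <- matrix(integer(0), ncol = 2,
                      dimnames = list(NULL, c("driver", "target")))
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) next
      if (!any(member[, i] & !member[, j])) {
        uncovered <- rbind(uncovered, c(i, j))
      }
    }
  }
  list(ok = nrow(uncovered) == 0L, uncovered = uncovered)
}

# units x channels logical membership matrix of a code.
rf_membership <- function(code) {
  L <- code$n_channels
  t(vapply(code$rfs, function(rf) seq_len(L) %in% rf, logical(L)))
}

#' Metabolic plus wiring cost of a combinatorial code
#'
#' Under a single-stimulus activity model the expected number of active-unit
#' events per presentation sweep is the total RF membership count
#' (`metabolic = sum over channels i of #units with i in RF`). Wiring counts
#' one input connection per RF lobe and one projection connection per
#' inhibited channel: each unit contributes `|RF| + (L - |RF|) = L` edges.
#'
#' @param code a `cosmi_code`.
#' @param alpha,beta non-negative weights of the metabolic and wiring
#'   components (defaults 1; the source framework states no weights).
#' @return an object of class `cosmi_cost`: list with `metabolic`, `wiring`,
#'   `total`, `alpha`, `beta`, `n_units`.
#' @examples
#' code_cost(copy_paste_code(6))  # metabolic 6, wiring 36
#' @export
code_cost <- function(code, alpha = 1, beta = 1) {
  stopifnot(inherits(code, "cosmi_code"), alpha >= 0, beta >= 0)
  L <- code$n_channels
  sizes <- lengths(code$rfs)
  metabolic <- sum(sizes)
  wiring <- sum((L - sizes) + sizes)   # = L * number of units
  structure(
    list(metabolic = metabolic, wiring = wiring,
         total = alpha * metabolic + beta * wiring,
         alpha = alpha, beta = beta, n_units = length(code$rfs)),
    class = "cosmi_cost"
  )
}

#' @export
print.cosmi_cost <- function(x, ...) {
  cat("COSMI code cost: total ", format(x$total),
      " (metabolic ", format(x$metabolic), " x alpha=", format(x$alpha),
      ", wiring ", format(x$wiring), " x beta=", format(x$beta),
      "; ", x$n_units, " units)\n", sep = "")
  invisible(x)
}

#' Search for a minimum-cost covered code
#'
#' Exhaustive mode is exact: it exploits the fact that pairwise coverage is
#' equivalent to the channel "incidence" vectors (which units each channel
#' drives) forming an antichain of distinct non-empty subsets of the unit
#' set, and that the cost decomposes as
#' `alpha * (total incidence weight) + beta * L * n_units`. For each feasible
#' unit count it finds a minimum-weight antichain of `L` subsets by
#' branch-and-bound. Greedy mode is a set-cover heuristic over ordered
#' channel pairs and never beats the exhaustive optimum.
#'
#' @param L number of channels (2..6 for exhaustive mode).
#' @param max_units maximum number of inhibitory units (<= 6 for exhaustive).
#' @param alpha,beta cost weights, see [code_cost()].
#' @param mode `"exhaustive"` (exact) or `"greedy"`.
#' @param seed integer; used only to break ties reproducibly in greedy mode.
#' @return list with `feasible` (logical), `code` (a `cosmi_code` or `NULL`),
#'   `cost` (a `cosmi_cost` or `NULL`) and `mode`.
#' @export
search_min_cost_code <- function(L, max_units, alpha = 1, beta = 1,
                                 mode = c("exhaustive", "greedy"),
                                 seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(L >= 2L, max_units >= 1L, alpha >= 0, beta >= 0)
  L <- as.integer(L)
  max_units <- as.integer(max_units)
  if (mode == "exhaustive") {
    if (L > 6L || max_units > 6L) {
      stop("exhaustive mode is guarded to L <= 6 and max_units <= 6")
    }
    res <- search_exhaustive(L, max_units, alpha, beta)
  } else {
    res <- search_greedy(L, max_units, alpha, beta, seed)
  }
  res$mode <- mode
  res
}

# Exact search via the antichain reformulation.
search_exhaustive <- function(L, max_units, alpha, beta) {
  best_cost <- Inf
  best_code <- NULL
  for (U in seq_len(max_units)) {
    if (choose(U, floor(U / 2)) < L) next   # Sperner: no antichain of size L
    w <- min_weight_antichain(U, L)
    if (is.null(w)) next
    total <- alpha * w$weight + beta * L * U
    if (total < best_cost - 1e-12) {
      # incidence sets -> RFs: unit u's RF = channels whose incidence holds u
      rfs <- lapply(seq_len(U), function(u) {
        which(vapply(w$sets, function(s) u %in% s, logical(1)))
      })
      best_cost <- total
      best_code <- cosmi_code(rfs, L)
    }
  }
  if (is.null(best_code)) {
    return(list(feasible = FALSE, code = NULL, cost = NULL))
  }
  list(feasible = TRUE, code = best_code,
       cost = code_cost(best_code, alpha, beta))
}

# Minimum-total-size antichain of `n_sets` distinct subsets of 1:U, subject to
# every unit appearing in >= 1 set (no unused unit) and no unit appearing in
# all sets (RF strictness). Branch-and-bound over subsets ordered by size.
min_weight_antichain <- function(U, n_sets) {
  subsets <- unlist(lapply(seq_len(U), function(k) {
    m <- utils::combn(U, k)
    lapply(seq_len(ncol(m)), function(j) m[, j])
  }), recursive = FALSE)
  sizes <- lengths(subsets)
  ord <- order(sizes)
  subsets <- subsets[ord]
  sizes <- sizes[ord]
  n_sub <- length(subsets)
  best <- list(weight = Inf, sets = NULL)

  comparable <- function(a, b) all(a %in% b) || all(b %in% a)

  rec <- function(start, chosen, weight) {
    k <- length(chosen)
    if (k == n_sets) {
      used <- unique(unlist(chosen))
      if (length(used) < U) return()             # some unit unused
      tab <- table(unlist(chosen))
      if (any(tab == n_sets)) return()           # unit in all sets -> RF = [L]
      if (weight < best$weight) best <<- list(weight = weight, sets = chosen)
      return()
    }
    remaining <- n_sets - k
    if (start > n_sub) return()
    # lower bound: remaining sets each at least as large as next available
    if (weight + remaining * sizes[start] >= best$weight) return()
    for (idx in start:n_sub) {
      if (weight + remaining * sizes[idx] >= best$weight) break
      s <- subsets[[idx]]
      if (k > 0 && any(vapply(chosen, comparable, logical(1), b = s))) next
      rec(idx + 1L, c(chosen, list(s)), weight + sizes[idx])
    }
  }
  rec(1L, list(), 0)
  if (is.infinite(best$weight)) NULL else best
}

# Greedy set cover over ordered pairs; candidates are all non-empty strict
# subsets of channels (L is small in practice).
search_greedy <- function(L, max_units, alpha, beta, seed) {
  if (L > 12L) stop("greedy candidate enumeration is guarded to L <= 12")
  cand <- unlist(lapply(seq_len(L - 1L), function(k) {
    m <- utils::combn(L, k)
    lapply(seq_len(ncol(m)), function(j) m[, j])
  }), recursive = FALSE)
  pairs <- expand.grid(driver = seq_len(L), target = seq_len(L))
  pairs <- pairs[pairs$driver != pairs$target, ]
  covers <- function(rf, drv, tgt) (drv %in% rf) & !(tgt %in% rf)
  cov_matrix <- vapply(cand, function(rf) {
    mapply(function(d, t) covers(rf, d, t), pairs$driver, pairs$target)
  }, logical(nrow(pairs)))
  uncovered <- rep(TRUE, nrow(pairs))
  chosen <- list()
  perm <- with_seed(seed, sample.int(length(cand)))  # reproducible tie-break
  while (any(uncovered) && length(chosen) < max_units) {
    gains <- colSums(cov_matrix & uncovered)
    unit_cost <- alpha * lengths(cand) + beta * L
    score <- gains / unit_cost
    score[gains == 0] <- -Inf
    best_idx <- perm[which.max(score[perm])]
    if (!is.finite(score[best_idx])) break
    chosen <- c(chosen, cand[best_idx])
    uncovered <- uncovered & !cov_matrix[, best_idx]
  }
  if (any(uncovered)) {
    return(list(feasible = FALSE, code = NULL, cost = NULL))
  }
  code <- cosmi_code(chosen, L)
  list(feasible = TRUE, code = code, cost = code_cost(code, alpha, beta))
}

#' @export
print.cosmi_code <- function(x, ...) {
  cat("COSMI code: ", length(x$rfs), " inhibitory units over ",
      x$n_channels, " channels\n", sep = "")
  for (u in seq_along(x$rfs)) {
    cat("  unit ", u, ": RF {", paste(x$rfs[[u]], collapse = ", "),
        "} -> inhibits {",
        paste(setdiff(seq_len(x$n_channels), x$rfs[[u]]), collapse = ", "),
        "}\n", sep = "")
  }
  invisible(x)
}

#' Write / read a combinatorial code as structured text
#'
#' Codes serialize as JSON: `{"n_channels": L, "rfs": [[...], ...]}`.
#'
#' @param code a `cosmi_code`.
#' @param path file path.
#' @return `read_cosmi_code` returns a `cosmi_code`; `write_cosmi_code`
#'   returns `path` invisibly.
#' @export
write_cosmi_code <- function(code, path) {
  stopifnot(inherits(code, "cosmi_code"))
  jsonlite::write_json(list(n_channels = code$n_channels, rfs = code$rfs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cosmi_code
#' @export
read_cosmi_code <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rfs <- x$rfs
  if (is.matrix(rfs)) rfs <- lapply(seq_len(nrow(rfs)), function(i) rfs[i, ])
  if (!is.list(rfs)) rfs <- as.list(rfs)
  cosmi_code(rfs, x$n_channels)
}
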