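#' Tokenize text
#'
#' Lower-cases, strips everything but letters, digits and apostrophes, and
#' splits on whitespace.
#'
#' @param x character vector
#' @return list of character token vectors (one per element of `x`)
#' @export
tokenize <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9']+", " ", x)
  strsplit(trimws(x), " +")
}

#' Contiguous n-grams of a token vector
#'
#' @param tokens character vector of tokens
#' @param n_max maximum n-gram length
#' @return character vector of all contiguous 1..n_max-grams
#' @export
ngrams <- function(tokens, n_max = 3) {
  m <- length(tokens)
  if (m == 0) return(character())
  out <- lapply(seq_len(min(n_max, m)), function(n) {
    starts <- seq_len(m - n + 1)
    vapply(starts, function(i) paste(tokens[i:(i + n - 1)], collapse = " "),
           character(1))
  })
  unlist(out)
}

#' Exact optimal transport between two discrete distributions
#'
#' Solves the transportation linear program
#' \eqn{\min_T \sum_{ij} T_{ij} C_{ij}} subject to row sums `a` and column
#' sums `b`, by the classical transportation-simplex method (north-west-corner
#' start, MODI pricing, cycle pivoting). Intended for the small problems
#' arising from bag-of-words transport; exact at machine precision.
#'
#' @param a,b non-negative weight vectors summing to the same total
#' @param cost |a| x |b| cost matrix
#' @return list with `cost` (optimal value) and `plan` (optimal transport
#'   matrix)
#' @export
ot_transport <- function(a, b, cost) {
  stopifnot(length(a) == nrow(cost), length(b) == ncol(cost),
            all(a >= 0), all(b >= 0))
  if (abs(sum(a) - sum(b)) > 1e-9 * max(sum(a), 1)) {
    stop("supplies and demands must balance")
  }
  m <- length(a); n <- length(b)
  if (m == 0 || n == 0) stop("empty distribution")
  plan <- matrix(0, m, n)
  basis <- matrix(FALSE, m, n)
  # north-west corner initial basic feasible solution
  ra <- a; rb <- b; i <- 1L; j <- 1L
  while (i <= m && j <= n) {
    q <- min(ra[i], rb[j])
    plan[i, j] <- q
    basis[i, j] <- TRUE
    ra[i] <- ra[i] - q; rb[j] <- rb[j] - q
    if (i == m && j == n) break
    if (ra[i] <= rb[j] && i < m) i <- i + 1L else j <- j + 1L
  }
  # ensure m + n - 1 basic cells (degenerate zeros allowed)
  while (sum(basis) < m + n - 1) {
    free <- which(!basis)
    basis[free[1]] <- TRUE
  }
  max_iter <- 200L * (m + n)
  for (iter in seq_len(max_iter)) {
    # duals from basis tree: u_i + v_j = c_ij on basic cells
    u <- rep(NA_real_, m); v <- rep(NA_real_, n)
    u[1] <- 0
    repeat {
      progressed <- FALSE
      for (idx in which(basis)) {
        bi <- (idx - 1L) %% m + 1L; bj <- (idx - 1L) %/% m + 1L
        if (!is.na(u[bi]) && is.na(v[bj])) {
          v[bj] <- cost[bi, bj] - u[bi]; progressed <- TRUE
        } else if (is.na(u[bi]) && !is.na(v[bj])) {
          u[bi] <- cost[bi, bj] - v[bj]; progressed <- TRUE
        }
      }
      if (!anyNA(u) && !anyNA(v)) break
      if (!progressed) { # disconnected tree (degenerate): patch with zero cell
        bi <- which(is.na(u))[1]
        if (!is.na(bi)) {
          bj <- which(!is.na(v))[1]
        } else {
          bj <- which(is.na(v))[1]; bi <- which(!is.na(u))[1]
        }
        basis[bi, bj] <- TRUE
      }
    }
    red <- cost - outer(u, v, "+")
    red[basis] <- 0
    ent <- which.min(red)
    if (red[ent] >= -1e-10) break
    ei <- (ent - 1L) %% m + 1L; ej <- (ent - 1L) %/% m + 1L
    cyc <- ot_find_cycle(basis, ei, ej)
    # minus positions are the 2nd, 4th, ... cells of the cycle
    minus <- cyc[seq(2, nrow(cyc), by = 2), , drop = FALSE]
    theta_idx <- which.min(plan[minus])
    theta <- plan[minus][theta_idx]
    sgn <- rep(c(1, -1), length.out = nrow(cyc))
    for (r in seq_len(nrow(cyc))) {
      plan[cyc[r, 1], cyc[r, 2]] <- plan[cyc[r, 1], cyc[r, 2]] + sgn[r] * theta
    }
    leave <- minus[theta_idx, ]
    basis[leave[1], leave[2]] <- FALSE
    basis[ei, ej] <- TRUE
  }
  list(cost = sum(plan * cost), plan = plan)
}

# unique alternating row/column cycle created by adding cell (ei, ej) to the
# basis tree; returned as a matrix of (i, j) cells starting at (ei, ej).
# Cells alternate row moves and column moves; the cycle closes with a column
# move within column ej back to the entering cell.
ot_find_cycle <- function(basis, ei, ej) {
  path <- list(c(ei, ej))
  found <- FALSE
  dfs <- function(i, j, along_row) {
    if (found) return()
    if (along_row) { # move within row i to another basic column
      for (jj in which(basis[i, ])) {
        if (jj == j) next
        path[[length(path) + 1]] <<- c(i, jj)
        dfs(i, jj, FALSE)
        if (found) return()
        path[[length(path)]] <<- NULL
      }
    } else { # move within column j: close if this is the entering column
      if (j == ej) { found <- TRUE; found <<- TRUE; return() }
      for (ii in which(basis[, j])) {
        if (ii == i) next
        path[[length(path) + 1]] <<- c(ii, j)
        dfs(ii, j, TRUE)
        if (found) return()
        path[[length(path)]] <<- NULL
      }
    }
  }
  dfs(ei, ej, TRUE)
  if (!found) stop("internal error: no pivot cycle found")
  do.call(rbind, path)
}

# collapse a token multiset to unique words + uniform instance weights,
# keeping only in-vocabulary words
bag_weights <- function(tokens, emb) {
  tokens <- tokens[tokens %in% rownames(emb)]
  if (length(tokens) == 0) return(NULL)
  tab <- table(tokens)
  list(words = names(tab), w = as.numeric(tab) / length(tokens))
}

#' Word mover's distance between two token bags
#'
#' The exact optimal-transport cost of moving the uniform bag-of-words
#' distribution of `doc_a` onto that of `doc_b` in the embedding space, with
#' Euclidean ground metric. Out-of-vocabulary tokens are dropped before
#' transport; a document with no in-vocabulary token has no distribution to
#' transport, which is signalled according to `on_empty`.
#'
#' @param doc_a,doc_b character token vectors (or length-1 strings, which are
#'   tokenized)
#' @param emb embedding matrix with word rownames
#' @param on_empty "error" (default) to raise a condition when a document is
#'   empty after vocabulary filtering, or "inf" to return `Inf` (useful in
#'   ranking contexts where such a document must simply never be selected)
#' @return non-negative distance; zero iff the two bags coincide
#' @export
wmd <- function(doc_a, doc_b, emb, on_empty = c("error", "inf")) {
  on_empty <- match.arg(on_empty)
  if (length(doc_a) == 1 && grepl(" ", doc_a)) doc_a <- tokenize(doc_a)[[1]]
  if (length(doc_b) == 1 && grepl(" ", doc_b)) doc_b <- tokenize(doc_b)[[1]]
  ba <- bag_weights(doc_a, emb)
  bb <- bag_weights(doc_b, emb)
  if (is.null(ba) || is.null(bb)) {
    if (on_empty == "inf") return(Inf)
    stop("word mover's distance undefined: document empty after vocabulary filtering")
  }
  va <- emb_lookup(emb, ba$words)
  vb <- emb_lookup(emb, bb$words)
  m <- nrow(va)
  cost <- as.matrix(stats::dist(rbind(va, vb)))[seq_len(m),
                                                m + seq_len(nrow(vb)),
                                                drop = FALSE]
  ot_transport(ba$w, bb$w, cost)$cost
}
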