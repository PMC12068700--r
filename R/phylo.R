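# Tree construction from alignment distances, Brownian-motion covariance,
# Pagel's lambda transform and its maximum-likelihood estimation.

#' Pairwise p-distances between aligned sequences
#'
#' Proportion of mismatched sites over columns where neither sequence has a
#' gap. A pair with zero comparable sites is an error.
#'
#' @param alignment a `res_alignment` with at least 3 sequences.
#' @return symmetric n x n matrix with zero diagonal, entries in `[0, 1]`,
#'   dimnames = sequence ids.
#' @export
pdistance <- function(alignment) {
  stopifnot(inherits(alignment, "res_alignment"))
  m <- alignment$rows
  n <- nrow(m)
  if (n < 3) stop("p-distance matrix needs at least 3 sequences")
  gap <- m == "-"
  d <- matrix(0, n, n, dimnames = list(alignment$ids, alignment$ids))
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      ok <- !gap[i, ] & !gap[k, ]
      if (!any(ok))
        stop(sprintf("no comparable (gap-free) sites between '%s' and '%s'",
                     alignment$ids[i], alignment$ids[k]))
      d[i, k] <- d[k, i] <- mean(m[i, ok] != m[k, ok])
    }
  }
  d
}

#' Neighbor-joining tree with midpoint rooting
#'
#' Standard Saitou-Nei agglomeration on a symmetric distance matrix: at each
#' step the pair minimizing the Q criterion
#' `Q(i,j) = (m - 2) d(i,j) - r(i) - r(j)` is joined, with branch lengths
#' from the rate-corrected formulas. Negative estimated branch lengths are
#' clamped to zero (the downstream Brownian-motion covariance requires
#' non-negative lengths) and the resulting unrooted tree is midpoint-rooted
#' on its longest leaf-to-leaf path. For additive input distances the
#' leaf-to-leaf path lengths of the result reproduce the input exactly.
#'
#' @param dm symmetric distance matrix with taxon dimnames.
#' @return rooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || max(abs(dm - t(dm))) > 1e-8)
    stop("distance matrix must be symmetric")
  n <- nrow(dm)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  labs <- rownames(dm)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))

  # agglomerate down to three active nodes; tips are 1..n, internal nodes
  # are numbered n+1, n+2, ... as created (ape convention: root is n+1,
  # ensured below by creating the final center node first in a relabeling)
  D <- unname(dm)
  act <- seq_len(n)          # phylo node id of each active row
  n_int <- 0L
  parent <- integer(0)
  child <- integer(0)
  plen <- numeric(0)
  while (length(act) > 3) {
    m <- length(act)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- arrayInd(which.min(Q), dim(Q))
    i <- min(ij); j <- max(ij)
    li <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    n_int <- n_int + 1L
    u <- n + n_int
    parent <- c(parent, u, u)
    child <- c(child, act[i], act[j])
    plen <- c(plen, li, lj)
    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    act <- c(act[keep], u)
  }
  # resolve the final three by the three-point formulas around a center
  n_int <- n_int + 1L
  u <- n + n_int
  l1 <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
  l2 <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
  l3 <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
  parent <- c(parent, u, u, u)
  child <- c(child, act[1], act[2], act[3])
  plen <- c(plen, l1, l2, l3)
  plen[plen < 0] <- 0

  # renumber internals so the trifurcating center is n+1 (ape root slot)
  old_int <- sort(unique(parent))
  map <- integer(n + n_int)
  map[seq_len(n)] <- seq_len(n)
  map[c(u, setdiff(old_int, u))] <- n + seq_len(n_int)
  edge <- cbind(map[parent], map[child])
  tr <- structure(list(edge = edge, edge.length = plen,
                       Nnode = n_int, tip.label = labs),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  validate_tree(midpoint_root(tr))
}

# Pairwise path lengths between all nodes of a (possibly unrooted) phylo
# tree, by accumulating depths from the structural root and subtracting
# twice the depth of the most recent common ancestor. Pure R.
.node_paths <- function(tr) {
  n <- length(tr$tip.label)
  n_nodes <- n + tr$Nnode
  par <- integer(n_nodes)
  par_len <- numeric(n_nodes)
  par[tr$edge[, 2]] <- tr$edge[, 1]
  par_len[tr$edge[, 2]] <- tr$edge.length
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]
  anc <- vector("list", n_nodes)
  depth <- numeric(n_nodes)
  for (v in seq_len(n_nodes)) {
    chain <- v
    d <- 0
    w <- v
    while (w != root) {
      d <- d + par_len[w]
      w <- par[w]
      chain <- c(chain, w)
    }
    anc[[v]] <- chain
    depth[v] <- d
  }
  list(par = par, par_len = par_len, root = root, anc = anc, depth = depth)
}

#' Midpoint-root an unrooted tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path,
#' splitting the edge on which the midpoint falls (or at the node it
#' coincides with). Leaf-to-leaf path lengths are preserved exactly.
#'
#' @param tr an [ape::phylo] tree (typically unrooted, from
#'   [neighbor_joining()]).
#' @return rooted [ape::phylo] tree.
#' @export
midpoint_root <- function(tr) {
  n <- length(tr$tip.label)
  info <- .node_paths(tr)
  # farthest leaf pair
  best <- c(1, 2); bestd <- -Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mrca_ij <- intersect(info$anc[[i]], info$anc[[j]])[1]
      dij <- info$depth[i] + info$depth[j] - 2 * info$depth[mrca_ij]
      if (dij > bestd) { bestd <- dij; best <- c(i, j) }
    }
  }
  a <- best[1]; b <- best[2]
  mrca_ab <- intersect(info$anc[[a]], info$anc[[b]])[1]
  path_a <- info$anc[[a]][seq_len(match(mrca_ab, info$anc[[a]]))]
  path_b <- info$anc[[b]][seq_len(match(mrca_ab, info$anc[[b]]))]
  path <- c(path_a, rev(path_b)[-1])   # a ... mrca ... b
  target <- bestd / 2
  # walk from a along the path until the midpoint is covered
  acc <- 0
  for (k in seq_len(length(path) - 1)) {
    u <- path[k]; v <- path[k + 1]
    # edge length between consecutive path nodes (one is parent of other)
    elen <- if (info$par[u] == v) info$par_len[u] else info$par_len[v]
    if (acc + elen >= target - 1e-12) {
      off <- target - acc          # distance from u along edge (u, v)
      return(.reroot_on_edge(tr, u, v, off))
    }
    acc <- acc + elen
  }
  .reroot_on_edge(tr, path[length(path) - 1], path[length(path)],
                  info$par_len[path[length(path) - 1]])
}

# Re-root tr by inserting a new root on the edge between adjacent nodes u
# and v, at distance `off` from u. Pure R: builds an adjacency list and
# redirects all edges away from the new root.
.reroot_on_edge <- function(tr, u, v, off) {
  n <- length(tr$tip.label)
  n_nodes <- n + tr$Nnode
  eidx <- which((tr$edge[, 1] == u & tr$edge[, 2] == v) |
                  (tr$edge[, 1] == v & tr$edge[, 2] == u))
  elen <- tr$edge.length[eidx[1]]
  off <- min(max(off, 0), elen)
  # adjacency with edge lengths, dropping the (u, v) edge
  adj <- vector("list", n_nodes + 1)
  wt <- vector("list", n_nodes + 1)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; c_ <- tr$edge[e, 2]
    if ((p == u && c_ == v) || (p == v && c_ == u)) next
    adj[[p]] <- c(adj[[p]], c_); wt[[p]] <- c(wt[[p]], tr$edge.length[e])
    adj[[c_]] <- c(adj[[c_]], p); wt[[c_]] <- c(wt[[c_]], tr$edge.length[e])
  }
  root <- n_nodes + 1L
  adj[[root]] <- c(u, v); wt[[root]] <- c(off, elen - off)
  adj[[u]] <- c(adj[[u]], root); wt[[u]] <- c(wt[[u]], off)
  adj[[v]] <- c(adj[[v]], root); wt[[v]] <- c(wt[[v]], elen - off)
  # orient away from root by iterative DFS
  new_par <- integer(n_nodes + 1)
  new_len <- numeric(n_nodes + 1)
  seen <- logical(n_nodes + 1)
  stack <- root; seen[root] <- TRUE
  order_nodes <- integer(0)
  while (length(stack) > 0) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_nodes <- c(order_nodes, x)
    nb <- adj[[x]]; wx <- wt[[x]]
    for (k in seq_along(nb)) {
      if (!seen[nb[k]]) {
        seen[nb[k]] <- TRUE
        new_par[nb[k]] <- x
        new_len[nb[k]] <- wx[k]
        stack <- c(stack, nb[k])
      }
    }
  }
  # drop degree-2 pass-through: if the old structural root became a
  # two-neighbour internal node it stays (harmless, zero extra length is
  # not introduced because its two incident edges are genuine)
  # renumber internals: root first, then the others in old order
  internals_old <- c(root, setdiff(which(seen), seq_len(n)))
  internals_old <- internals_old[!duplicated(internals_old)]
  map <- integer(n_nodes + 1)
  map[seq_len(n)] <- seq_len(n)
  map[internals_old] <- n + seq_along(internals_old)
  kids <- which(seen & seq_len(n_nodes + 1) != root)
  edge <- cbind(map[new_par[kids]], map[kids])
  out <- structure(list(edge = edge, edge.length = new_len[kids],
                        Nnode = length(internals_old),
                        tip.label = tr$tip.label),
                   class = "phylo")
  out <- ape::collapse.singles(out)
  ape::reorder.phylo(out, "cladewise")
}

#' Brownian-motion covariance of a rooted tree
#'
#' Entry (i, j) is the branch length shared from the root down to the most
#' recent common ancestor of tips i and j; the diagonal holds root-to-tip
#' path lengths.
#'
#' @param tree rooted [ape::phylo] tree with non-negative branch lengths.
#' @return symmetric n x n matrix with tip labels as dimnames.
#' @export
bm_covariance <- function(tree) {
  tree <- validate_tree(tree)
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a BM covariance
#'
#' Multiplies off-diagonal entries by `lambda` in `[0, 1]`, leaving the
#' diagonal unchanged. `lambda = 1` is the identity; `lambda = 0` removes all
#' shared history (independent tips).
#'
#' @param V covariance matrix from [bm_covariance()].
#' @param lambda value in `[0, 1]`.
#' @return transformed covariance matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 ||
      is.na(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  Vl
}

# Profiled log-likelihood of trait ~ N(mu * 1, sigma2 * V) with mu and
# sigma2 at their closed-form ML values; returns -Inf if chol fails.
.profile_loglik <- function(V, y) {
  n <- length(y)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf))
  z1 <- backsolve(ch, rep(1, n), transpose = TRUE)
  zy <- backsolve(ch, y, transpose = TRUE)
  mu <- sum(z1 * zy) / sum(z1 * z1)
  zr <- zy - mu * z1
  sigma2 <- sum(zr^2) / n
  ll <- -0.5 * n * log(2 * pi * sigma2) - sum(log(diag(ch))) - 0.5 * n
  list(loglik = ll, mu = mu, sigma2 = sigma2)
}

#' Maximum-likelihood estimate of Pagel's lambda for a continuous trait
#'
#' Fits `trait ~ N(mu * 1, sigma2 * V(lambda))` where `V(lambda)` is the
#' Brownian-motion covariance of the tree with off-diagonals scaled by
#' lambda. `mu` and `sigma2` are profiled in closed form; lambda is found by
#' bounded 1-D optimization on `[0, 1]` (tolerance 1e-6) started from the
#' best point of an 11-point grid, with both boundaries checked explicitly.
#'
#' @param tree rooted [ape::phylo] tree (at least 4 tips).
#' @param trait numeric vector, named by tip label (or in tip order).
#' @return object of class `res_signal`: list with `lambda_hat`,
#'   `sigma2_hat`, `loglik` (at the optimum), `loglik_star` (at lambda = 0),
#'   and `boundary` (`TRUE` when the estimate sits at 0 or 1 within 1e-4).
#' @export
estimate_lambda <- function(tree, trait) {
  tree <- validate_tree(tree)
  n <- ape::Ntip(tree)
  if (n < 4) stop("lambda estimation needs at least 4 taxa")
  if (!is.null(names(trait))) {
    names(trait) <- normalize_taxon(names(trait))
    if (!all(tree$tip.label %in% names(trait)))
      stop("trait vector is missing taxa: ",
           paste(setdiff(tree$tip.label, names(trait)), collapse = ", "))
    trait <- trait[tree$tip.label]
  } else if (length(trait) != n) {
    stop("unnamed trait vector must have one value per tip")
  }
  if (var(trait) == 0) stop("trait is constant; lambda is undefined")
  V <- bm_covariance(tree)
  obj <- function(lam) .profile_loglik(lambda_transform(V, lam), trait)$loglik
  grid <- seq(0, 1, by = 0.1)
  gvals <- vapply(grid, obj, numeric(1))
  if (all(!is.finite(gvals)))
    stop(sprintf(
      "V(lambda) singular across the grid (condition number %.3g at lambda=1)",
      kappa(V)))
  best <- grid[which.max(gvals)]
  lo <- max(0, best - 0.1)
  hi <- min(1, best + 0.1)
  opt <- optimize(obj, interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
  cand <- rbind(c(opt$maximum, opt$objective),
                c(0, gvals[1]),
                c(1, gvals[length(gvals)]),
                c(best, max(gvals)))
  lam_hat <- cand[which.max(cand[, 2]), 1]
  fit <- .profile_loglik(lambda_transform(V, lam_hat), trait)
  structure(list(lambda_hat = lam_hat,
                 sigma2_hat = fit$sigma2,
                 loglik = fit$loglik,
                 loglik_star = gvals[1],
                 boundary = lam_hat < 1e-4 || lam_hat > 1 - 1e-4),
            class = "res_signal")
}

#' @export
print.res_signal <- function(x, ...) {
  cat(sprintf(
    "res_signal: lambda_hat = %.6f%s, sigma2_hat = %.4g, logLik = %.4f (logLik at lambda=0: %.4f)\n",
    x$lambda_hat, if (x$boundary) " [boundary]" else "",
    x$sigma2_hat, x$loglik, x$loglik_star))
  invisible(x)
}
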