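# Shared fixture builders and independent oracles.

# Build a res_alignment from a character vector of equal-length strings.
aln_from_strings <- function(seqs, ids = paste0("s", seq_along(seqs))) {
  rows <- do.call(rbind, strsplit(seqs, ""))
  new_alignment(rows, ids = ids)
}

# Write a FASTA file from named sequences; returns the path.
write_fasta_tmp <- function(seqs, ids = names(seqs)) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

# Independent GLS oracle by explicit normal equations (textbook matrix
# inversion), deliberately different from the Cholesky-whitening code path.
gls_oracle <- function(X, y, V) {
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  n <- nrow(X)
  p <- ncol(X)
  sigma2 <- drop(t(r) %*% Vi %*% r) / (n - p)
  covb <- sigma2 * solve(XtVi %*% X)
  se <- unname(sqrt(diag(covb)))
  t_stat <- unname(drop(beta)) / se
  list(beta = unname(drop(beta)), se = se, t = t_stat,
       p = 2 * pt(-abs(t_stat), n - p))
}

# Random positive-definite covariance matrix.
random_pd <- function(n) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + diag(n)
}

# A small fixed rooted tree used across tests.
tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# Independent leaf-to-leaf path-length matrix computed by climbing parent
# chains in plain R (oracle for tree reconstruction and round-trips).
path_dist <- function(tr) {
  n <- length(tr$tip.label)
  n_nodes <- n + tr$Nnode
  par <- integer(n_nodes)
  plen <- numeric(n_nodes)
  par[tr$edge[, 2]] <- tr$edge[, 1]
  plen[tr$edge[, 2]] <- tr$edge.length
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]
  chains <- lapply(seq_len(n), function(v) {
    ch <- v; d <- 0
    while (v != root) { d <- c(d, d[length(d)] + plen[v]); v <- par[v]; ch <- c(ch, v) }
    list(nodes = ch, cum = d)
  })
  out <- matrix(0, n, n, dimnames = list(tr$tip.label, tr$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ci <- chains[[i]]; cj <- chains[[j]]
      m <- ci$nodes[ci$nodes %in% cj$nodes][1]
      out[i, j] <- out[j, i] <-
        ci$cum[match(m, ci$nodes)] + cj$cum[match(m, cj$nodes)]
    }
  }
  out
}
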