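# Independently coded oracles used to cross-check the package
# implementations. These deliberately re-derive each quantity from its
# definition rather than calling the functions under test.

# --- PCIT brute force -------------------------------------------------------
# Direct transcription of the trio rule: for every ordered trio, compute
# the three first-order partials and the mean |partial/direct| tolerance,
# then eliminate any edge dominated by a third node.
pcit_oracle <- function(r) {
  n <- nrow(r)
  sig <- matrix(TRUE, n, n)
  diag(sig) <- FALSE
  pc <- function(rxy, rxz, ryz) {
    den <- (1 - rxz^2) * (1 - ryz^2)
    if (den < 1e-12) return(0)
    (rxy - rxz * ryz) / sqrt(den)
  }
  rat <- function(p, d) if (d == 0) 0 else abs(p / d)
  if (n < 3) return(sig)
  for (x in 1:(n - 2)) for (y in (x + 1):(n - 1)) for (z in (y + 1):n) {
    pxy <- pc(r[x, y], r[x, z], r[y, z])
    pxz <- pc(r[x, z], r[x, y], r[y, z])
    pyz <- pc(r[y, z], r[x, y], r[x, z])
    eps <- (rat(pxy, r[x, y]) + rat(pxz, r[x, z]) + rat(pyz, r[y, z])) / 3
    if (abs(r[x, y]) <= abs(eps * r[x, z]) && abs(r[x, y]) <= abs(eps * r[y, z]))
      sig[x, y] <- sig[y, x] <- FALSE
    if (abs(r[x, z]) <= abs(eps * r[x, y]) && abs(r[x, z]) <= abs(eps * r[y, z]))
      sig[x, z] <- sig[z, x] <- FALSE
    if (abs(r[y, z]) <= abs(eps * r[x, y]) && abs(r[y, z]) <= abs(eps * r[x, z]))
      sig[y, z] <- sig[z, y] <- FALSE
  }
  sig
}

random_cor_matrix <- function(n, n_samples = 10) {
  x <- matrix(rnorm(n_samples * n), n_samples, n)
  r <- cor(x)
  dimnames(r) <- list(paste0("g", 1:n), paste0("g", 1:n))
  r
}

# --- betweenness by shortest-path enumeration -------------------------------
# For each ordered pair (s, t), enumerate every shortest path by recursive
# descent over a BFS distance labelling and accumulate, per intermediate
# node, the fraction of shortest paths through it.
betweenness_oracle <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  bfs_dist <- function(s) {
    d <- rep(Inf, n); d[s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in which(adj[v, ] == 1)) if (d[w] == Inf) {
        d[w] <- d[v] + 1; q <- c(q, w)
      }
    }
    d
  }
  all_shortest <- function(s, t, d) {
    if (s == t) return(list(s))
    out <- list()
    for (v in which(adj[t, ] == 1)) {
      if (d[v] == d[t] - 1) {
        for (p in all_shortest(s, v, d)) out[[length(out) + 1]] <- c(p, t)
      }
    }
    out
  }
  for (s in 1:(n - 1)) {
    d <- bfs_dist(s)
    for (t in (s + 1):n) {
      if (!is.finite(d[t])) next
      paths <- all_shortest(s, t, d)
      np <- length(paths)
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        btw[inner] <- btw[inner] + 1 / np
      }
    }
  }
  btw
}

# --- duplex structures by exhaustive enumeration ----------------------------
# Every intermolecular structure is a pair of equal-length strictly
# increasing index sets; energy re-derived from the parameter object.
duplex_oracle <- function(q_seq, t_seq, params) {
  code <- function(s) strsplit(s, "")[[1]]
  qc <- code(q_seq); tc <- code(t_seq)
  m <- length(qc); n <- length(tc)
  pair_name <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% c("AU", "UA", "CG", "GC", "GU", "UG")) p else NA_character_
  }
  # target is read 3'->5' against the query: reverse its indices
  energy <- function(qi, tj) {
    k <- length(qi)
    pn <- character(k)
    for (h in seq_len(k)) {
      pn[h] <- pair_name(qc[qi[h]], tc[tj[h]])
      if (is.na(pn[h])) return(NA_real_)
    }
    e <- params$duplex_init
    if (k > 1) for (h in 2:k) {
      g1 <- qi[h] - qi[h - 1] - 1
      g2 <- (tj[h - 1] - tj[h]) - 1   # target indices decrease
      if (g1 < 0 || g2 < 0 || g1 > params$max_loop || g2 > params$max_loop)
        return(NA_real_)
      if (g1 == 0 && g2 == 0) e <- e + params$stack[pn[h - 1], pn[h]]
      else if (g1 == 0 || g2 == 0) e <- e + params$bulge_open + params$bulge_ext * (g1 + g2)
      else e <- e + params$iloop_open + params$iloop_ext * (g1 + g2)
    }
    e
  }
  subsets <- function(n, k) if (k == 0) list(integer(0)) else combn(n, k, simplify = FALSE)
  best <- 0
  for (k in 1:min(m, n)) {
    qs <- subsets(m, k)
    ts <- subsets(n, k)
    for (qi in qs) for (tj in ts) {
      e <- energy(qi, rev(tj))  # antiparallel: query ascending, target descending
      if (!is.na(e) && e < best) best <- e
    }
  }
  best
}

# --- seed sites by regex set arithmetic -------------------------------------
seed_oracle <- function(mirna, target) {
  rc <- function(s) {
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  core <- rc(substr(mirna, 2, 7))
  m8c <- c(A = "U", C = "G", G = "C", U = "A")[substr(mirna, 8, 8)]
  find <- function(pat) {
    g <- gregexpr(pat, target, perl = TRUE)[[1]]
    if (g[1] == -1) integer(0) else as.integer(g)
  }
  pos_core <- find(paste0("(?=", core, ")"))
  pos_m8 <- find(paste0("(?=", m8c, core, ")")) + 1L  # core start after the m8 match
  pos_a1 <- find(paste0("(?=", core, "A)"))
  out <- NULL
  for (p in pos_core) {
    m8 <- p %in% pos_m8
    a1 <- p %in% pos_a1
    if (m8 && a1) row <- c("8mer", p - 2L)
    else if (m8) row <- c("7mer-m8", p - 2L)
    else if (a1) row <- c("7mer-A1", p - 1L)
    else row <- c("6mer", p - 1L)
    out <- rbind(out, data.frame(site_type = row[1],
                                 start = as.integer(row[2]),
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out)) data.frame(site_type = character(0), start = integer(0)) else out
}

# --- components by union-find ----------------------------------------------
components_oracle <- function(nodes, edges) {
  parent <- setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(edges))) {
    a <- find(edges$node_a[i]); b <- find(edges$node_b[i])
    if (a != b) parent[[b]] <- a
  }
  roots <- vapply(nodes, find, character(1))
  unname(lapply(split(nodes, roots), sort))
}

random_rna_str <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
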