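# Statistical-parsimony haplotype networks and step-path metrics.

#' Pairwise mutational steps between haplotypes
#'
#' Hamming differences counted only over columns where both haplotypes carry
#' an unambiguous base; gap or ambiguity columns are excluded pairwise.
#'
#' @param haps a `haplotype_set`.
#' @return symmetric integer matrix of step counts.
#' @export
pairwise_steps <- function(haps) {
  seqs <- haps$haplotypes
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1)
    stop("haplotypes differ in length")
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(m) <- names(seqs)
  ok <- matrix(m %in% BASES, nrow = nrow(m))
  n <- nrow(m)
  out <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      use <- ok[i, ] & ok[j, ]
      out[i, j] <- out[j, i] <- sum(m[i, use] != m[j, use])
    }
  out
}

#' Statistical-parsimony connection limit
#'
#' The largest number of mutational steps for which a pairwise connection is
#' still considered parsimonious at confidence `alpha`. The probability that
#' a pair differing at `j` of `L` sites is parsimonious (every segregating
#' site experienced exactly one substitution, and no superimposed change hit
#' an invariant site) is evaluated under a Jukes-Cantor multiple-hit model:
#' the expected number of substitutions per site along the connecting path is
#' estimated from the observed difference proportion by the JC inversion, the
#' number of hits per site is taken as Poisson, and the probability of at
#' most one hit is computed conditionally on the observed
#' segregating/invariant pattern. `max_steps` is the largest `j` whose
#' parsimony probability is at least `alpha` (never below 1).
#'
#' @param L comparable sequence length in nucleotides.
#' @param alpha confidence level (default 0.95).
#' @return object of class `parsimony_limit`: list with `L`, `alpha`,
#'   `max_steps`, `prob` (parsimony probability at 1..max_steps+1).
#' @export
parsimony_connection_limit <- function(L, alpha = 0.95) {
  if (L < 1) stop("L must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  probs <- numeric(0)
  j <- 0
  repeat {
    j <- j + 1
    probs[j] <- parsimony_probability(L, j)
    if (probs[j] < alpha || j >= L) break
  }
  max_steps <- max(1L, sum(probs >= alpha))
  structure(list(L = L, alpha = alpha, max_steps = max_steps, prob = probs),
            class = "parsimony_limit")
}

#' Parsimony probability of a j-step connection
#'
#' Probability that every site experienced at most one substitution given
#' that `j` of `L` sites differ, with the path divergence estimated by the
#' Jukes-Cantor inversion of `p = j/L` and per-site hit counts Poisson.
#' This is the per-pair quantity thresholded by
#' [parsimony_connection_limit()].
#'
#' @param L comparable sequence length in nucleotides.
#' @param j number of observed differences.
#' @return probability in `[0, 1]`.
#' @export
parsimony_probability <- function(L, j) {
  p <- j / L
  if (p >= 0.75) return(0)
  lam <- -0.75 * log(1 - 4 * p / 3)
  if (lam == 0) return(1)
  p_diff <- 0.75 * (1 - exp(-4 * lam / 3))   # equals p by construction
  p_same <- 1 - p_diff
  r_diff <- lam * exp(-lam) / p_diff          # P(1 hit | site differs)
  r_same <- exp(-lam) / p_same                # P(0 hits | site identical)
  r_diff^j * r_same^(L - j)
}

#' @export
print.parsimony_limit <- function(x, ...) {
  cat(sprintf("parsimony limit: %d steps at %.0f%% (L = %d)\n",
              x$max_steps, 100 * x$alpha, x$L))
  invisible(x)
}

#' Build a statistical-parsimony haplotype network
#'
#' Haplotype pairs are joined in nondecreasing step order (agglomerating
#' components, never creating cycles) while the step count does not exceed
#' the parsimony limit; each multi-step join is expanded into unit edges
#' through flagged unsampled intermediate nodes (abstract, no sequence). With
#' `force_connect`, residual components are then joined through their
#' minimum inter-component pair regardless of the limit, leaving all
#' within-component paths untouched.
#'
#' @param haps a `haplotype_set`.
#' @param limit a `parsimony_limit` (or NULL to derive one from haplotype
#'   length at alpha 0.95).
#' @param force_connect join residual components past the limit
#'   (default TRUE).
#' @return object of class `haplotype_network`: list with `graph` (igraph;
#'   vertex attributes `name`, `freq`, `sampled`), `haplotypes`, `limit`.
#' @export
build_network <- function(haps, limit = NULL, force_connect = TRUE) {
  if (!length(haps$haplotypes)) stop("need at least 1 haplotype")
  if (is.null(limit))
    limit <- parsimony_connection_limit(nchar(haps$haplotypes[[1]]))
  steps <- pairwise_steps(haps)
  hn <- names(haps$haplotypes)
  n <- length(hn)
  # candidate pairs sorted by steps, then lexicographically for determinism
  pairs <- if (n > 1) {
    idx <- which(upper.tri(steps), arr.ind = TRUE)
    ord <- order(steps[idx], idx[, 1], idx[, 2])
    idx[ord, , drop = FALSE]
  } else matrix(integer(0), 0, 2)
  comp <- seq_len(n)
  chosen <- list()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    s <- steps[i, j]
    if (comp[i] == comp[j]) next
    if (s > limit$max_steps && !force_connect) next
    if (s > limit$max_steps) {
      # defer over-limit joins until all within-limit joins are done
      next
    }
    chosen[[length(chosen) + 1]] <- c(i, j, s)
    comp[comp == comp[j]] <- comp[i]
  }
  if (force_connect) {
    repeat {
      if (length(unique(comp)) == 1) break
      best <- NULL
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        if (comp[i] != comp[j]) { best <- c(i, j, steps[i, j]); break }
      }
      if (is.null(best)) break
      chosen[[length(chosen) + 1]] <- best
      comp[comp == comp[best[2]]] <- comp[best[1]]
    }
  }
  # expand chosen joins into unit edges through intermediates
  vnames <- hn
  sampled <- rep(TRUE, n)
  freq <- as.numeric(haps$counts)
  edges <- character(0)
  inter <- 0
  for (e in chosen) {
    a <- hn[e[1]]; b <- hn[e[2]]; s <- e[3]
    if (s <= 1) {
      edges <- c(edges, a, b)
    } else {
      prev <- a
      for (k in seq_len(s - 1)) {
        inter <- inter + 1
        nm <- sprintf("x%d", inter)
        vnames <- c(vnames, nm); sampled <- c(sampled, FALSE)
        freq <- c(freq, 0)
        edges <- c(edges, prev, nm)
        prev <- nm
      }
      edges <- c(edges, prev, b)
    }
  }
  g <- igraph::make_empty_graph(n = length(vnames), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = vnames)
  g <- igraph::set_vertex_attr(g, "freq", value = freq)
  g <- igraph::set_vertex_attr(g, "sampled", value = sampled)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  structure(list(graph = g, haplotypes = haps, limit = limit),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  ns <- sum(igraph::V(x$graph)$sampled)
  cat(sprintf(
    "haplotype network: %d sampled haplotypes, %d intermediates, %d edges, %d component(s)\n",
    ns, igraph::vcount(x$graph) - ns, igraph::ecount(x$graph),
    igraph::components(x$graph)$no))
  invisible(x)
}

#' Step-path metrics over a haplotype network
#'
#' Shortest-path step counts (breadth-first over unit edges) between sampled
#' haplotypes; per-subgroup diameter (longest shortest path among members)
#' and count of alignment columns variable among member haplotype sequences;
#' pairwise minimum separation between subgroups. Unreachable pairs (separate
#' components) are Inf.
#'
#' @param net a `haplotype_network`.
#' @param subgroups named list mapping a subgroup label to a character vector
#'   of haplotype names.
#' @return list with `steps` (matrix over sampled haplotypes), `subgroups`
#'   (data.frame label, n_haplotypes, diameter, variable_positions),
#'   `separation` (matrix of minimum between-subgroup step counts).
#' @export
path_metrics <- function(net, subgroups = list()) {
  g <- net$graph
  sampled <- igraph::V(g)$name[igraph::V(g)$sampled]
  all_named <- unique(unlist(subgroups))
  missing_nodes <- setdiff(all_named, sampled)
  if (length(missing_nodes))
    stop("haplotype(s) not in network: ", paste(missing_nodes, collapse = ", "))
  steps <- igraph::distances(g, v = sampled, to = sampled)
  seqs <- net$haplotypes$haplotypes
  sub <- do.call(rbind, lapply(names(subgroups), function(lb) {
    mem <- subgroups[[lb]]
    dia <- if (length(mem) > 1) max(steps[mem, mem]) else 0
    vp <- if (length(mem) > 1) {
      mm <- do.call(rbind, strsplit(unname(seqs[mem]), ""))
      sum(apply(mm, 2, function(col) length(unique(col)) > 1))
    } else 0
    data.frame(label = lb, n_haplotypes = length(mem), diameter = dia,
               variable_positions = vp, stringsAsFactors = FALSE)
  }))
  k <- length(subgroups)
  sep <- matrix(NA_real_, k, k, dimnames = list(names(subgroups),
                                                names(subgroups)))
  if (k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      sep[i, j] <- if (i == j) 0 else
        min(steps[subgroups[[i]], subgroups[[j]], drop = FALSE])
    }
  list(steps = steps, subgroups = sub, separation = sep)
}

#' Export a network edge list
#'
#' Merges runs of unit edges through intermediates back into haplotype-to-
#' haplotype records with a step count, and writes a TSV.
#' @param net a `haplotype_network`.
#' @param path output TSV path (NULL to just return the data.frame).
#' @return data.frame with columns `from`, `to`, `steps`.
#' @export
export_edge_list <- function(net, path = NULL) {
  g <- net$graph
  sampled <- igraph::V(g)$name[igraph::V(g)$sampled]
  # intermediates have degree 2 and lie on exactly one run
  rows <- list()
  seen <- character(0)
  for (a in sampled) {
    nb <- igraph::neighbors(g, a)
    for (v in nb) {
      prev <- a; cur <- igraph::V(g)$name[v]; s <- 1
      while (!igraph::V(g)$sampled[match(cur, igraph::V(g)$name)]) {
        nxt <- setdiff(igraph::V(g)$name[igraph::neighbors(g, cur)], prev)
        prev <- cur; cur <- nxt[1]; s <- s + 1
      }
      key <- paste(sort(c(a, cur)), s, collapse = "|")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        rows[[length(rows) + 1]] <- data.frame(from = min(a, cur),
                                               to = max(a, cur), steps = s,
                                               stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(from = character(), to = character(), steps = integer())
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  out
}
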