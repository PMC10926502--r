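# Tamura-Nei (1993) distances, neighbor joining, jackknife support, and
# clade-composition reports.

#' Tamura-Nei (TN93) pairwise distances
#'
#' Computes the TN93 closed-form distance for every sequence pair, separating
#' the two transition classes (A<->G, C<->T) from transversions, with base
#' frequencies estimated empirically. Sites where either sequence carries a
#' gap or ambiguity code are deleted pairwise when `pair_deletion` is TRUE
#' (always pairwise here; the flag controls whether frequencies are pooled
#' over the pair or over the whole alignment).
#'
#' A pair whose log arguments are non-positive (too divergent for the model)
#' is flagged saturated and its distance set to NA.
#'
#' @param aln a `barcode_aln`.
#' @param pair_deletion if TRUE (default) base frequencies are pooled over
#'   the comparable sites of each pair; if FALSE, over the whole alignment.
#' @return object of class `tn93_dist`: list with `d` (symmetric matrix),
#'   `saturated` (logical matrix), `labels`.
#' @export
tn93_distance <- function(aln, pair_deletion = TRUE) {
  m <- unclass(aln)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 sequences")
  labs <- rownames(m)
  ok <- matrix(m %in% BASES, nrow = n)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  sat <- matrix(FALSE, n, n, dimnames = list(labs, labs))
  glob_freq <- NULL
  if (!pair_deletion) {
    calls <- m[ok]
    glob_freq <- table(factor(calls, levels = BASES)) / length(calls)
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- ok[i, ] & ok[j, ]
    if (!any(use))
      stop(sprintf("no comparable sites between '%s' and '%s'",
                   labs[i], labs[j]))
    a <- m[i, use]; b <- m[j, use]
    nn <- length(a)
    diff <- a != b
    ag <- (a == "A" & b == "G") | (a == "G" & b == "A")
    ct <- (a == "C" & b == "T") | (a == "T" & b == "C")
    P1 <- sum(ag) / nn
    P2 <- sum(ct) / nn
    Q <- sum(diff & !ag & !ct) / nn
    if (pair_deletion) {
      calls <- c(a, b)
      f <- table(factor(calls, levels = BASES)) / length(calls)
    } else f <- glob_freq
    pA <- f[["A"]]; pC <- f[["C"]]; pG <- f[["G"]]; pT <- f[["T"]]
    pR <- pA + pG; pY <- pC + pT
    k1 <- 2 * pA * pG / pR
    k2 <- 2 * pC * pT / pY
    w1 <- 1 - P1 / k1 - Q / (2 * pR)
    w2 <- 1 - P2 / k2 - Q / (2 * pY)
    w3 <- 1 - Q / (2 * pR * pY)
    if (!is.finite(w1) || !is.finite(w2) || !is.finite(w3) ||
        w1 <= 0 || w2 <= 0 || w3 <= 0) {
      sat[i, j] <- sat[j, i] <- TRUE
      d[i, j] <- d[j, i] <- NA_real_
    } else {
      dd <- -k1 * log(w1) - k2 * log(w2) -
        2 * (pR * pY - pA * pG * pY / pR - pC * pT * pR / pY) * log(w3)
      d[i, j] <- d[j, i] <- dd
    }
  }
  structure(list(d = d, saturated = sat, labels = labs),
            class = "tn93_dist")
}

#' @export
print.tn93_dist <- function(x, ...) {
  cat(sprintf("TN93 distance matrix: %d labels, %d saturated pairs\n",
              length(x$labels), sum(x$saturated) / 2))
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration. Ties in the Q criterion are broken by
#' the pair whose smaller original-label index is lowest (then by the larger
#' index), making the output deterministic. Negative branch lengths are
#' clamped to zero with the deficit moved to the sister branch.
#'
#' @param D a `tn93_dist` or a plain symmetric numeric matrix with
#'   dimnames.
#' @return object of class `supported_tree`: list with `tree` (an
#'   [ape::read.tree()] phylo), `support` (NULL here), `outgroup` (NULL).
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "tn93_dist")) {
    if (any(D$saturated))
      stop("saturated pairs present; exclude those sequences before NJ")
    M <- D$d
  } else M <- as.matrix(D)
  n <- nrow(M)
  if (n < 3) stop("need at least 3 labels")
  labs <- rownames(M)
  # newick fragment and minimal original leaf index per active node
  frag <- labs
  minidx <- seq_len(n)
  active <- seq_len(n)
  repeat {
    k <- length(active)
    if (k == 3) break
    Msub <- M[active, active, drop = FALSE]
    r <- rowSums(Msub)
    best <- NULL; bestQ <- Inf; bestkey <- c(Inf, Inf)
    for (ii in 1:(k - 1)) for (jj in (ii + 1):k) {
      q <- (k - 2) * Msub[ii, jj] - r[ii] - r[jj]
      key <- sort(c(minidx[active[ii]], minidx[active[jj]]))
      if (q < bestQ - 1e-12 ||
          (abs(q - bestQ) <= 1e-12 &&
           (key[1] < bestkey[1] ||
            (key[1] == bestkey[1] && key[2] < bestkey[2])))) {
        bestQ <- q; best <- c(ii, jj); bestkey <- key
      }
    }
    i <- active[best[1]]; j <- active[best[2]]
    dij <- M[i, j]
    li <- dij / 2 + (sum(M[i, active]) - sum(M[j, active])) / (2 * (k - 2))
    lj <- dij - li
    # clamp negatives, moving the deficit to the sister branch
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    if (li < 0) li <- 0
    if (lj < 0) lj <- 0
    others <- setdiff(active, c(i, j))
    newd <- (M[i, others] + M[j, others] - dij) / 2
    u <- i  # reuse slot i for the merged node
    M[u, others] <- newd; M[others, u] <- newd
    frag[u] <- sprintf("(%s:%.17g,%s:%.17g)", frag[i], li, frag[j], lj)
    minidx[u] <- min(minidx[i], minidx[j])
    active <- setdiff(active, j)
  }
  a <- active[1]; b <- active[2]; c_ <- active[3]
  la <- (M[a, b] + M[a, c_] - M[b, c_]) / 2
  lb <- M[a, b] - la
  lc <- M[a, c_] - la
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 frag[a], la, frag[b], lb, frag[c_], lc)
  tree <- ape::read.tree(text = nwk)
  structure(list(tree = tree, support = NULL, outgroup = NULL),
            class = "supported_tree")
}

#' @export
print.supported_tree <- function(x, ...) {
  cat(sprintf("tree with %d tips%s\n", length(x$tree$tip.label),
              if (is.null(x$support)) "" else
                sprintf(", %d supported bipartitions", length(x$support))))
  invisible(x)
}

# Canonical internal bipartitions of an unrooted phylo: each represented as
# the sorted tip set on the side NOT containing the alphabetically first tip,
# encoded as a single string.
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  parts <- ape::prop.part(tree)
  out <- character(0)
  for (p in parts) {
    side <- tree$tip.label[p]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) >= 2 && length(side) <= length(tips) - 2)
      out <- c(out, paste(sort(side), collapse = "\r"))
  }
  unique(out)
}

#' Jackknife branch support
#'
#' Each replicate deletes `ceiling(deletion * L)` alignment columns without
#' replacement, rebuilds the TN93 + NJ tree, and the frequency (%) with which
#' each internal bipartition of the full-data tree recurs annotates that
#' tree. Replicates in which the distance computation fails (e.g. a pair left
#' with no comparable sites) are counted as supporting no bipartition. The
#' same seed yields identical supports.
#'
#' @param aln a `barcode_aln`.
#' @param replicates number of replicates (default 1000).
#' @param deletion fraction of columns deleted per replicate (default 0.5).
#' @param seed integer RNG seed.
#' @return a `supported_tree` whose `support` is a named numeric vector
#'   (percentages) keyed by canonical bipartition.
#' @export
jackknife_support <- function(aln, replicates = 1000, deletion = 0.5,
                              seed = 1) {
  if (replicates < 1) stop("replicates must be >= 1")
  full <- neighbor_joining(tn93_distance(aln))
  bips <- tree_bipartitions(full$tree)
  counts <- stats::setNames(numeric(length(bips)), bips)
  L <- ncol(aln)
  ndel <- ceiling(deletion * L)
  set.seed(seed)
  for (r in seq_len(replicates)) {
    drop <- sample.int(L, ndel)
    sub <- structure(unclass(aln)[, -drop, drop = FALSE],
                     class = "barcode_aln")
    rep_tree <- tryCatch(neighbor_joining(tn93_distance(sub)),
                         error = function(e) NULL)
    if (is.null(rep_tree)) next
    rb <- tree_bipartitions(rep_tree$tree)
    hit <- bips %in% rb
    counts[hit] <- counts[hit] + 1
  }
  full$support <- 100 * counts / replicates
  full
}

#' Clade composition and label monophyly on a tree
#'
#' For every internal node (on the tree rooted at the declared outgroup when
#' present, else at the first tip) reports the percentage of terminals per
#' label; for every label, whether its members form a single clade on the
#' unrooted tree (singletons are trivially monophyletic).
#'
#' @param tree a `supported_tree` or `phylo`.
#' @param table a `sample_table` covering the tips.
#' @param label_field one of `species`, `subspecies`, `group`, `locality`.
#' @return list with `composition` (data.frame node, label, pct, n) and
#'   `monophyly` (named logical).
#' @export
clade_composition <- function(tree, table,
                              label_field = c("species", "subspecies",
                                              "group", "locality")) {
  label_field <- match.arg(label_field)
  phy <- if (inherits(tree, "supported_tree")) tree$tree else tree
  table <- as_sample_table(as.data.frame(table))
  lab <- stats::setNames(table[[label_field]], table$sample_id)
  if (any(!(phy$tip.label %in% names(lab))) ||
      any(is.na(lab[phy$tip.label])) || any(lab[phy$tip.label] == ""))
    stop("every leaf must carry a non-empty label")
  tiplab <- lab[phy$tip.label]
  og <- intersect(group_ids(table, "outgroup"), phy$tip.label)
  rooted <- if (length(og)) ape::root(phy, outgroup = og,
                                      resolve.root = TRUE) else phy
  parts <- ape::prop.part(rooted)
  comp <- do.call(rbind, lapply(seq_along(parts), function(i) {
    members <- rooted$tip.label[parts[[i]]]
    tl <- lab[members]
    tt <- table(tl)
    data.frame(node = i, label = names(tt),
               pct = 100 * as.numeric(tt) / length(members),
               n = as.numeric(tt), stringsAsFactors = FALSE)
  }))
  sides <- strsplit(tree_bipartitions(phy), "\r", fixed = TRUE)
  ntip <- length(phy$tip.label)
  mono <- vapply(unique(tiplab), function(lv) {
    mem <- sort(phy$tip.label[tiplab == lv])
    if (length(mem) <= 1 || length(mem) >= ntip - 1) return(TRUE)
    other <- sort(setdiff(phy$tip.label, mem))
    any(vapply(sides, function(s) identical(s, mem) || identical(s, other),
               TRUE))
  }, TRUE)
  list(composition = comp, monophyly = mono)
}
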