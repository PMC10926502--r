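# Oligonucleotide thermodynamics: the unified nearest-neighbor model
# (SantaLucia 1998, PNAS 95:1460, as tabulated by Allawi & SantaLucia 1997,
# Biochemistry 36:10581) and the salt-adjusted GC melting-temperature
# formula. The two engines serve different purposes and are kept separate:
# the NN model drives design constraints; the GC formula reproduces the
# primer-table Tm reports.

# Unified NN parameters: dH kcal/mol, dS cal/(mol K), dG37 kcal/mol, keyed by
# the top-strand dimer (antiparallel Watson-Crick complement underneath).
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
           GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)
NN_DG <- c(AA = -1.00, AT = -0.88, TA = -0.58, CA = -1.45, GT = -1.44,
           CT = -1.28, GA = -1.30, CG = -2.17, GC = -2.24, GG = -1.84,
           TT = -1.00, TG = -1.45, AC = -1.44, AG = -1.28, TC = -1.30,
           CC = -1.84)
# Duplex initiation terms, per terminal base pair.
NN_INIT <- list(
  GC = c(dH = 0.1, dS = -2.8, dG = 0.98),
  AT = c(dH = 2.3, dS = 4.1, dG = 1.03)
)
GAS_R <- 1.987  # cal/(mol K)

check_unambiguous <- function(seq, min_len = 2) {
  b <- strsplit(toupper(seq), "")[[1]]
  if (length(b) < min_len)
    stop("sequence too short (need >= ", min_len, " nt)")
  if (any(!(b %in% BASES)))
    stop("ambiguous or non-nucleotide character in sequence: ",
         paste(unique(b[!(b %in% BASES)]), collapse = ", "))
  b
}

#' Reverse complement
#' @param seq a DNA string (unambiguous or IUPAC; codes are complemented).
#' @return the reverse complement string.
#' @export
reverse_complement <- function(seq) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(toupper(seq), "")[[1]]), collapse = ""))
}

nn_sums <- function(bases) {
  dimers <- paste0(bases[-length(bases)], bases[-1])
  ends <- c(bases[1], bases[length(bases)])
  init <- lapply(ends, function(e)
    if (e %in% c("G", "C")) NN_INIT$GC else NN_INIT$AT)
  list(dH = sum(NN_DH[dimers]) + init[[1]]["dH"] + init[[2]]["dH"],
       dS = sum(NN_DS[dimers]) + init[[1]]["dS"] + init[[2]]["dS"],
       dG = sum(NN_DG[dimers]) + init[[1]]["dG"] + init[[2]]["dG"])
}

#' Nearest-neighbor duplex melting temperature
#'
#' Unified NN stack sums with duplex-initiation terms;
#' `Tm = 1000 dH / (dS + R ln(CT/x)) - 273.15` with symmetry factor `x = 4`
#' for non-self-complementary duplexes and `x = 1` (plus the symmetry entropy
#' term -1.4 cal/(mol K)) for self-complementary ones. Monovalent salt enters
#' through the entropic correction `dS + 0.368 (N-1) ln[Na+]`; divalent
#' cations in excess of dNTPs are converted to a monovalent equivalent as
#' `[Na+]_eq = [Na+] + 120 sqrt([Mg2+] - [dNTP])` with concentrations in mM
#' (von Ahsen, Wittwer & Schuetz 2001, Clin Chem 47:1956 - the conversion
#' used by Primer3).
#'
#' @param seq oligo sequence, 5'->3', unambiguous.
#' @param mono molar monovalent cation concentration (default 0.05).
#' @param div molar divalent cation concentration (default 0.0015).
#' @param dntp molar dNTP concentration (default 6e-4).
#' @param ct molar total strand concentration (default 5e-8).
#' @return Tm in degrees C.
#' @export
tm_nearest_neighbor <- function(seq, mono = 0.05, div = 0.0015,
                                dntp = 6e-4, ct = 5e-8) {
  b <- check_unambiguous(seq, 2)
  s <- nn_sums(b)
  dH <- s$dH; dS <- s$dS
  selfcomp <- identical(paste(b, collapse = ""),
                        reverse_complement(paste(b, collapse = "")))
  x <- 4
  if (selfcomp) { x <- 1; dS <- dS - 1.4 }
  na_eq <- mono + 120 * sqrt(max(div - dntp, 0) * 1000) / 1000
  dS <- dS + 0.368 * (length(b) - 1) * log(na_eq)
  unname(1000 * dH / (dS + GAS_R * log(ct / x)) - 273.15)
}

#' Salt-adjusted GC melting temperature
#'
#' `Tm = 100.5 + 41 (nGC/N) - 820/N + 16.6 log10([Na+])`, reported to one
#' decimal. This composition-and-length formula is the engine used for the
#' tabulated primer Tm values; design-constraint checks use
#' [tm_nearest_neighbor()].
#'
#' @param seq oligo sequence (>= 8 nt, unambiguous).
#' @param Na molar monovalent cation concentration (default 0.05).
#' @return Tm in degrees C, rounded to one decimal.
#' @export
tm_salt_adjusted <- function(seq, Na = 0.05) {
  b <- check_unambiguous(seq, 8)
  n <- length(b)
  ngc <- sum(b %in% c("G", "C"))
  round(100.5 + 41 * (ngc / n) - 820 / n + 16.6 * log10(Na), 1)
}

#' GC content (%)
#' @param seq DNA string.
#' @return percentage of G+C among unambiguous bases.
#' @export
gc_percent <- function(seq) {
  b <- strsplit(toupper(seq), "")[[1]]
  100 * sum(b %in% c("G", "C")) / sum(b %in% BASES)
}

# Duplex dG37 (kcal/mol) of a fully matched stretch, with initiation.
duplex_dg37 <- function(seq) {
  b <- check_unambiguous(seq, 2)
  unname(nn_sums(b)$dG)
}

# Best antiparallel complementarity between a (5'->3') and b (5'->3'):
# at each offset, a[i] pairs with b read 3'->5'. Returns the maximum total
# match count (annealing score) and the best contiguous matched run.
dimer_alignment <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- rev(strsplit(toupper(b), "")[[1]])  # 3'->5'
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  na_ <- length(av); nb <- length(bv)
  best_total <- 0L
  best_run <- list(len = 0L, a_start = NA_integer_)
  for (off in (-(nb - 1)):(na_ - 1)) {
    i <- max(1, 1 + off); j <- i - off
    total <- 0L; run <- 0L; run_start <- NA_integer_
    while (i <= na_ && j <= nb) {
      if (!is.na(comp[av[i]]) && comp[[av[i]]] == bv[j]) {
        total <- total + 1L
        if (run == 0L) run_start <- i
        run <- run + 1L
        if (run > best_run$len)
          best_run <- list(len = run, a_start = run_start)
      } else run <- 0L
      i <- i + 1L; j <- j + 1L
    }
    if (total > best_total) best_total <- total
  }
  list(score = best_total, run = best_run)
}

#' Screen an oligo for secondary structure
#'
#' Self- and hetero-dimers are scored as the nearest-neighbor duplex Tm of
#' the best ungapped complementary stretch between the sequence and its
#' partner (itself for self-dimer), aligned antiparallel over every offset.
#' The hairpin score is the longest intramolecular antiparallel stem with a
#' loop of at least 3 bases. The self-annealing score is the maximal total
#' complementarity over all offsets. Poly-X is the longest single-base run.
#' 3'-stability is the magnitude of the NN duplex dG37 of the 5 terminal
#' 3'-end bases (larger = a stickier 3' end, more prone to mispriming).
#'
#' @param oligo sequence 5'->3'.
#' @param partner optional partner sequence for the hetero-dimer score.
#' @param mono,div,dntp,ct conditions passed to [tm_nearest_neighbor()].
#' @return list of class `structure_scores`: `hairpin`, `self_dimer_tm`,
#'   `self_annealing`, `hetero_dimer_tm` (NA if no partner), `poly_x`,
#'   `three_prime_stability` (kcal/mol magnitude).
#' @export
structure_screen <- function(oligo, partner = NULL, mono = 0.05,
                             div = 0.0015, dntp = 6e-4, ct = 5e-8) {
  b <- check_unambiguous(oligo, 2)
  n <- length(b)
  runs <- rle(b)
  poly_x <- max(runs$lengths)
  stretch_tm <- function(al) {
    if (al$run$len < 2) return(0)
    sub <- paste(b[al$run$a_start:(al$run$a_start + al$run$len - 1)],
                 collapse = "")
    max(0, tm_nearest_neighbor(sub, mono, div, dntp, ct))
  }
  self_al <- dimer_alignment(oligo, oligo)
  het <- NA_real_
  if (!is.null(partner)) {
    check_unambiguous(partner, 2)
    het_al <- dimer_alignment(oligo, partner)
    pb <- strsplit(toupper(oligo), "")[[1]]
    het <- if (het_al$run$len >= 2) {
      sub <- paste(pb[het_al$run$a_start:
                        (het_al$run$a_start + het_al$run$len - 1)],
                   collapse = "")
      max(0, tm_nearest_neighbor(sub, mono, div, dntp, ct))
    } else 0
  }
  # hairpin: stem positions i..i+s-1 pair with j..j+s-1 reversed, loop >= 3
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  hairpin <- 0L
  for (i in seq_len(n - 1)) for (j in n:(i + 1)) {
    if (j - i - 1 < 3) next
    s <- 0L
    while (i + s < j - s && (j - s) - (i + s) - 1 >= 3 &&
           comp[[b[i + s]]] == b[j - s]) s <- s + 1L
    if (s > hairpin) hairpin <- s
  }
  tp <- if (n >= 5) abs(duplex_dg37(paste(b[(n - 4):n], collapse = ""))) else
    abs(duplex_dg37(paste(b, collapse = "")))
  structure(list(hairpin = as.integer(hairpin),
                 self_dimer_tm = stretch_tm(self_al),
                 self_annealing = self_al$score,
                 hetero_dimer_tm = het,
                 poly_x = as.integer(poly_x),
                 three_prime_stability = tp),
            class = "structure_scores")
}

#' @export
print.structure_scores <- function(x, ...) {
  cat(sprintf(
    "structure: hairpin %d, self-dimer Tm %.1f, self-annealing %d, poly-X %d, 3' dG %.2f\n",
    x$hairpin, x$self_dimer_tm, x$self_annealing, x$poly_x,
    x$three_prime_stability))
  invisible(x)
}
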