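# Primer melting temperature, search windows and pair selection.
#
# Primer candidates are rows of a data.frame with columns
#   sequence       5'->3' on the primer strand
#   genomic_start  0-based genomic coordinate of the 5' base
#   strand         "+" (forward) or "-" (reverse)
#   length, tm, gc
#   role           "amplification" or "sequencing"
#   side           "upstream" or "downstream"

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K), keyed by the top-strand dinucleotide.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# initiation terms per terminal base
.NN_INIT_DH <- c(A = 2.3, T = 2.3, C = 0.1, G = 0.1)
.NN_INIT_DS <- c(A = 4.1, T = 4.1, C = -2.8, G = -2.8)

#' Oligonucleotide melting temperature
#'
#' Two methods: `"wallace"` (Tm = 2(A+T) + 4(G+C), the quick rule for
#' short oligos) and `"nn"` (nearest-neighbor thermodynamics with the
#' SantaLucia 1998 unified parameter set, monovalent-salt entropy
#' correction `dS + 0.368 (N-1) ln[Na+]`, and Tm = 1000 dH / (dS + R
#' ln(C/4)) - 273.15). Both are deterministic.
#'
#' @param sequence Character vector of primer sequences (>= 8 nt, ACGT).
#' @param method `"nn"` (default) or `"wallace"`.
#' @param params List of nn-method parameters: `conc_nM` total oligo
#'   concentration in nM (default 50) and `na_mM` monovalent cation
#'   concentration in mM (default 50).
#' @return Numeric vector of temperatures in degrees Celsius.
#' @examples
#' meltingTemp("ACGTACGTACGTACGTACGT", method = "wallace")  # 60
#' @export
meltingTemp <- function(sequence, method = c("nn", "wallace"),
                        params = list(conc_nM = 50, na_mM = 50)) {
  method <- match.arg(method)
  if (any(nchar(sequence) < 8L))
    .inputError("sequence must be at least 8 nt for a meaningful Tm")
  if (any(!.isDnaAcgt(sequence)))
    .inputError("sequence must contain only A, C, G, T")
  vapply(sequence, function(s) {
    b <- strsplit(s, "")[[1]]
    if (method == "wallace") {
      at <- sum(b %in% c("A", "T")); gc <- length(b) - at
      return(2 * at + 4 * gc)
    }
    n <- length(b)
    dinucs <- paste0(b[-n], b[-1])
    dH <- sum(.NN_DH[dinucs]) + .NN_INIT_DH[[b[1]]] + .NN_INIT_DH[[b[n]]]
    dS <- sum(.NN_DS[dinucs]) + .NN_INIT_DS[[b[1]]] + .NN_INIT_DS[[b[n]]]
    na <- (if (is.null(params$na_mM)) 50 else params$na_mM) / 1000
    ct <- (if (is.null(params$conc_nM)) 50 else params$conc_nM) * 1e-9
    dS <- dS + 0.368 * (n - 1) * log(na)
    1000 * dH / (dS + 1.987 * log(ct / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' GC fraction of sequences
#' @param sequence Character vector of DNA strings.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
gcFraction <- function(sequence) {
  vapply(sequence, function(s) {
    b <- strsplit(s, "")[[1]]
    sum(b %in% c("G", "C")) / length(b)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Primer search windows around a cut position
#'
#' Four half-open genomic intervals anchored on the cut: amplification
#' primers are sought 1000-1200 bp away on both sides (far windows),
#' sequencing primers 400-600 bp away (near windows). A primer's 5' end
#' must lie inside its window. Windows are clipped to the locus bounds; a
#' window falling entirely outside comes back empty with a warning.
#'
#' @param cut_pos Genomic cut coordinate (0-based).
#' @param locus_bounds Length-2 integer vector, half-open locus interval.
#' @param config A [designConfig()] list (window distances are taken from
#'   `amp_window` and `seq_window`).
#' @return Named list of four entries (`upstream_far`, `upstream_near`,
#'   `downstream_near`, `downstream_far`), each a list with `start`,
#'   `end`, `role` and `side`.
#' @export
primerWindows <- function(cut_pos, locus_bounds, config = designConfig()) {
  cut_pos <- as.integer(cut_pos)
  lb <- as.integer(locus_bounds)
  if (cut_pos < lb[1] || cut_pos >= lb[2])
    .rangeError("cut position %d outside locus [%d, %d)", cut_pos,
                lb[1], lb[2])
  far <- as.integer(config$amp_window)    # c(1000, 1200)
  near <- as.integer(config$seq_window)   # c(400, 600)
  raw <- list(
    upstream_far    = c(cut_pos - far[2],  cut_pos - far[1]),
    upstream_near   = c(cut_pos - near[2], cut_pos - near[1]),
    downstream_near = c(cut_pos + near[1], cut_pos + near[2]),
    downstream_far  = c(cut_pos + far[1],  cut_pos + far[2]))
  role <- c(upstream_far = "amplification", upstream_near = "sequencing",
            downstream_near = "sequencing", downstream_far = "amplification")
  side <- c(upstream_far = "upstream", upstream_near = "upstream",
            downstream_near = "downstream", downstream_far = "downstream")
  out <- list()
  for (nm in names(raw)) {
    s <- max(raw[[nm]][1], lb[1]); e <- min(raw[[nm]][2], lb[2])
    if (e <= s) {
      .cdWarn("primer window '%s' falls outside the locus and is empty", nm)
      s <- e <- raw[[nm]][1]
      s <- e  # zero-length marker
    }
    out[[nm]] <- list(start = as.integer(s), end = as.integer(e),
                      role = role[[nm]], side = side[[nm]])
  }
  out
}

# 3'-end self-complementarity: length of the longest suffix of the primer
# that is its own reverse complement, i.e. the longest perfect antiparallel
# anneal of two copies' 3' ends.
.self3Complementarity <- function(s) {
  b <- strsplit(s, "")[[1]]
  n <- length(b)
  best <- 0L
  for (k in seq_len(min(n, 12L))) {
    suf <- b[(n - k + 1L):n]
    if (all(suf == .COMP[rev(suf)])) best <- k
  }
  best
}

# Enumerate and filter primer candidates whose 5' end lies in one window.
# Filters apply in a fixed order (alphabet, GC, homopolymer, Tm, 3'
# self-complementarity) with per-filter failure counts in `diag`.
.windowCandidates <- function(seqchr, locus_offset, win, config, diag) {
  lens <- as.integer(config$primer_len)       # e.g. 18:27
  tmr <- config$primer_tm; gcr <- config$primer_gc
  locus_len <- nchar(seqchr)
  fivep <- seq.int(win$start, length.out = max(win$end - win$start, 0L))
  fivep <- fivep[fivep >= locus_offset & fivep < locus_offset + locus_len]
  if (length(fivep) == 0L) return(NULL)
  grid <- expand.grid(p = fivep, L = lens)
  if (win$side == "upstream") {                # forward primer on '+'
    s0 <- grid$p - locus_offset; e0 <- s0 + grid$L
    ok <- e0 <= locus_len
    seqp <- substring(seqchr, s0[ok] + 1L, e0[ok])
  } else {                                     # reverse primer on '-'
    e0 <- grid$p - locus_offset + 1L; s0 <- e0 - grid$L
    ok <- s0 >= 0L
    seqp <- revComp(substring(seqchr, s0[ok] + 1L, e0[ok]))
  }
  grid <- grid[ok, , drop = FALSE]
  diag$n_enumerated <- diag$n_enumerated + length(seqp)

  pass <- !grepl("N", seqp, fixed = TRUE)
  diag$fail_alphabet <- diag$fail_alphabet + sum(!pass)
  grid <- grid[pass, , drop = FALSE]; seqp <- seqp[pass]

  gc <- (nchar(seqp) - nchar(gsub("[GC]", "", seqp))) / nchar(seqp)
  pass <- gc >= gcr[1] & gc <= gcr[2]
  diag$fail_gc <- diag$fail_gc + sum(!pass)
  grid <- grid[pass, , drop = FALSE]; seqp <- seqp[pass]; gc <- gc[pass]

  pass <- !grepl(sprintf("(.)\\1{%d}", config$max_homopolymer), seqp)
  diag$fail_homopolymer <- diag$fail_homopolymer + sum(!pass)
  grid <- grid[pass, , drop = FALSE]; seqp <- seqp[pass]; gc <- gc[pass]

  if (length(seqp) == 0L) return(NULL)
  tm <- meltingTemp(seqp, method = config$tm_method,
                    params = config$tm_params)
  pass <- tm >= tmr[1] & tm <= tmr[2]
  diag$fail_tm <- diag$fail_tm + sum(!pass)
  grid <- grid[pass, , drop = FALSE]; seqp <- seqp[pass]
  gc <- gc[pass]; tm <- tm[pass]

  pass <- vapply(seqp, .self3Complementarity, integer(1),
                 USE.NAMES = FALSE) <= config$max_self3
  diag$fail_self3 <- diag$fail_self3 + sum(!pass)
  grid <- grid[pass, , drop = FALSE]; seqp <- seqp[pass]
  gc <- gc[pass]; tm <- tm[pass]

  if (length(seqp) == 0L) return(NULL)
  data.frame(sequence = seqp, genomic_start = grid$p,
             strand = if (win$side == "upstream") "+" else "-",
             length = grid$L, tm = tm, gc = gc, role = win$role,
             side = win$side, stringsAsFactors = FALSE)
}

#' Enumerate, filter and pair primers in the search windows
#'
#' Candidates of every configured length whose 5' end lies in a window
#' are filtered on Tm range, GC range, maximum homopolymer run and 3'-end
#' self-complementarity. Upstream far-window forward primers are paired
#' with downstream far-window reverse primers (amplification pairs,
#' ranked by `|Tm_f - Tm_r|` then by product size closest to the
#' configured optimum); sequencing primers from the near windows are
#' single oligos ranked by closeness of Tm to the middle of the Tm range.
#'
#' @param assembly A [GenomeAssembly-class].
#' @param contig Contig name.
#' @param windows Window list from [primerWindows()].
#' @param config A [designConfig()] list.
#' @return List with elements `pairs` (amplification [PrimerPair rows:
#'   forward/reverse columns prefixed `fwd_`/`rev_`, `product_size`,
#'   `tm_delta`]), `sequencing` (candidate table), `candidates` (all
#'   passing candidates) and `diagnostics` (per-filter failure counts).
#' @export
pickPrimerPairs <- function(assembly, contig, windows,
                            config = designConfig()) {
  if (config$primer_tm[1] > config$primer_tm[2])
    .configError("primer Tm range has min > max")
  if (config$primer_gc[1] > config$primer_gc[2])
    .configError("primer GC range has min > max")
  lo <- min(vapply(windows, `[[`, integer(1), "start"))
  hi <- max(vapply(windows, `[[`, integer(1), "end"))
  lo <- max(0L, lo - max(config$primer_len))
  hi <- min(contigLengths(assembly)[[contig]], hi + max(config$primer_len))
  seqchr <- extractRegion(assembly, contig, lo, hi, "+")
  diag <- new.env()
  diag$n_enumerated <- 0L
  for (f in c("fail_alphabet", "fail_gc", "fail_homopolymer", "fail_tm",
              "fail_self3")) assign(f, 0L, envir = diag)
  cand <- list()
  for (nm in names(windows)) {
    w <- windows[[nm]]
    if (w$end <= w$start) next
    cand[[nm]] <- .windowCandidates(seqchr, lo, w, config, diag)
  }
  cand <- do.call(rbind, cand[!vapply(cand, is.null, logical(1))])
  diagnostics <- mget(c("n_enumerated", "fail_alphabet", "fail_gc",
                        "fail_homopolymer", "fail_tm", "fail_self3"),
                      envir = diag)
  empty <- function(msg) {
    .cdWarn("%s (enumerated %d; failed: tm %d, gc %d, homopolymer %d, self3 %d, alphabet %d)",
            msg, diagnostics$n_enumerated, diagnostics$fail_tm,
            diagnostics$fail_gc, diagnostics$fail_homopolymer,
            diagnostics$fail_self3, diagnostics$fail_alphabet)
  }
  if (is.null(cand)) {
    empty("no primer candidates pass the filters")
    return(list(pairs = NULL, sequencing = NULL, candidates = NULL,
                diagnostics = diagnostics))
  }
  rownames(cand) <- NULL

  fw <- cand[cand$role == "amplification" & cand$strand == "+", , drop = FALSE]
  rv <- cand[cand$role == "amplification" & cand$strand == "-", , drop = FALSE]
  pairs <- NULL
  if (nrow(fw) > 0L && nrow(rv) > 0L) {
    grid <- expand.grid(f = seq_len(nrow(fw)), r = seq_len(nrow(rv)))
    product <- (rv$genomic_start[grid$r] + 1L) - fw$genomic_start[grid$f]
    tm_delta <- abs(fw$tm[grid$f] - rv$tm[grid$r])
    pairs <- data.frame(
      fwd_sequence = fw$sequence[grid$f],
      fwd_genomic_start = fw$genomic_start[grid$f],
      fwd_length = fw$length[grid$f], fwd_tm = fw$tm[grid$f],
      fwd_gc = fw$gc[grid$f],
      rev_sequence = rv$sequence[grid$r],
      rev_genomic_start = rv$genomic_start[grid$r],
      rev_length = rv$length[grid$r], rev_tm = rv$tm[grid$r],
      rev_gc = rv$gc[grid$r],
      product_size = as.integer(product), tm_delta = tm_delta,
      stringsAsFactors = FALSE)
    ord <- order(pairs$tm_delta, abs(pairs$product_size - config$product_opt),
                 pairs$fwd_genomic_start, pairs$rev_genomic_start,
                 method = "radix")
    pairs <- pairs[ord, , drop = FALSE][seq_len(min(config$top_k, nrow(pairs))), ,
                                        drop = FALSE]
    rownames(pairs) <- NULL
  } else {
    empty("no amplification primer pair available")
  }

  seqc <- cand[cand$role == "sequencing", , drop = FALSE]
  if (nrow(seqc) > 0L) {
    mid <- mean(config$primer_tm)
    ord <- order(abs(seqc$tm - mid), seqc$genomic_start, seqc$strand,
                 method = "radix")
    seqc <- seqc[ord, , drop = FALSE]
    keep <- unlist(lapply(split(seq_len(nrow(seqc)), seqc$side),
                          function(i) i[seq_len(min(config$top_k, length(i)))]))
    seqc <- seqc[sort(keep), , drop = FALSE]
    ord <- order(abs(seqc$tm - mid), seqc$genomic_start, seqc$strand,
                 method = "radix")
    seqc <- seqc[ord, , drop = FALSE]
    rownames(seqc) <- NULL
  } else {
    seqc <- NULL
    empty("no sequencing primer candidates pass the filters")
  }

  list(pairs = pairs, sequencing = seqc, candidates = cand,
       diagnostics = diagnostics)
}
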