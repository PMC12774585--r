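# Position-weight efficiency scoring and composite guide ranking.

#' Read an efficiency matrix from a plain-text file
#'
#' Format: optional `#` comment lines (kept as provenance), a header row
#' `A C G T`, then 20 whitespace-delimited rows of 4 numbers — row i
#' holds the weights of bases A/C/G/T at protospacer position i (1 =
#' PAM-distal, 20 = PAM-proximal).
#'
#' @param path Path to the matrix file.
#' @param name Name recorded on the object (defaults to the file name).
#' @return An [EfficiencyMatrix-class].
#' @export
readEfficiencyMatrix <- function(path, name = basename(path)) {
  if (!file.exists(path)) .formatError("matrix file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  prov <- sub("^#\\s?", "", lines[startsWith(lines, "#")])
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) != 21L)
    .formatError("expected header + 20 rows in '%s', found %d non-comment lines",
                 path, length(body))
  hdr <- strsplit(trimws(body[1]), "\\s+")[[1]]
  if (!identical(hdr, c("A", "C", "G", "T")))
    .formatError("matrix header must be 'A C G T' in '%s'", path)
  vals <- lapply(body[-1], function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (length(v) != 4L || any(is.na(v)))
      .formatError("malformed matrix row '%s' in '%s'", l, path)
    v
  })
  w <- do.call(rbind, vals)
  colnames(w) <- c("A", "C", "G", "T")
  methods::new("EfficiencyMatrix", weights = w, name = name,
               provenance = prov)
}

#' The package's default efficiency matrix
#'
#' Loads the synthetic stand-in matrix shipped under
#' `inst/extdata/efficiency_matrix_default.txt`. It encodes generic,
#' hand-set positional base preferences and makes scores reproducible; it
#' does not reproduce any published efficiency model (see its provenance
#' header). Swap in your own matrix with [readEfficiencyMatrix()].
#'
#' @return An [EfficiencyMatrix-class].
#' @export
defaultEfficiencyMatrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "efficiency_matrix_default.txt",
                          package = "crisprDonor", mustWork = TRUE)
      cache <<- readEfficiencyMatrix(path, name = "default-synthetic")
    }
    cache
  }
})

#' Score protospacers with a position-weight matrix
#'
#' The score is the sum over positions 1..20 of the weight of the base at
#' that position. Higher is better; the scale is that of the matrix.
#'
#' @param protospacer Character vector of 20-nt ACGT sequences.
#' @param matrix An [EfficiencyMatrix-class] (default matrix when `NULL`).
#' @return Numeric vector of scores.
#' @export
efficiencyScore <- function(protospacer, matrix = NULL) {
  if (is.null(matrix)) matrix <- defaultEfficiencyMatrix()
  stopifnot(is(matrix, "EfficiencyMatrix"))
  if (any(nchar(protospacer) != 20L))
    .inputError("protospacer must be exactly 20 nt")
  if (any(!.isDnaAcgt(protospacer)))
    .inputError("protospacer must contain only A, C, G, T")
  w <- matrix@weights
  vapply(protospacer, function(p) {
    bases <- strsplit(p, "")[[1]]
    sum(w[cbind(1:20, match(bases, c("A", "C", "G", "T")))])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Rank annotated guide sites
#'
#' Composite deterministic ordering: sites with an exact off-target
#' (`ot0 > 0`) are demoted to the end (they are flagged, not removed);
#' within each group, efficiency descending, then total off-target count
#' (`ot1 + ot2 + ot3`) ascending, then `|anchor_distance|` ascending,
#' then cut position, PAM position and strand (`"+"` first) for byte-
#' reproducible output. Ranking is stable: re-ranking a ranked table is
#' the identity.
#'
#' @param sites Guide-site data.frame annotated by [annotateGuides()].
#' @return The same table, reordered, with a `rank` column prepended.
#' @export
rankGuides <- function(sites) {
  if (nrow(sites) == 0L) {
    sites$rank <- integer(0)
    return(sites)
  }
  need <- c("efficiency", "ot_total", "has_exact_offtarget",
            "anchor_distance")
  missing <- setdiff(need, names(sites))
  if (length(missing) > 0L)
    .inputError("sites must be annotated before ranking (missing: %s)",
                paste(missing, collapse = ", "))
  ord <- order(sites$has_exact_offtarget, -sites$efficiency, sites$ot_total,
               abs(sites$anchor_distance), sites$cut_pos, sites$pam_start,
               sites$strand, method = "radix")
  out <- sites[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$rank <- seq_len(nrow(out))
  out[, c("rank", setdiff(names(out), "rank"))]
}
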