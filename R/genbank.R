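# GenBank flat-file serialization of AssemblyMap objects.
#
# Hand-rolled on purpose: the writer/parser pair is part of the package
# contract (round-trip identity on sequence, topology and features), and
# output must be byte-stable across runs (fixed LOCUS date, no
# timestamps) so identical designs produce identical files.

.GB_DATE <- "01-JAN-2026"   # fixed: output files must be byte-reproducible

#' Construct an AssemblyMap
#'
#' @param name Record name.
#' @param sequence DNA string (uppercased on input).
#' @param topology `"linear"` or `"circular"`.
#' @param features Feature data.frame (columns `start`, `end`, `strand`,
#'   `type`, `label`, `note`; internal 0-based half-open coordinates).
#' @param provenance Character vector of free-text notes.
#' @param metadata Optional bookkeeping list (not serialized).
#' @return An [AssemblyMap-class].
#' @export
assemblyMap <- function(name, sequence, topology = "linear",
                        features = .emptyFeatures(),
                        provenance = character(0), metadata = list()) {
  name <- gsub("\\s+", "_", name)  # LOCUS names cannot contain whitespace
  methods::new("AssemblyMap", name = name, sequence = toupper(sequence),
               topology = topology, features = features,
               provenance = provenance, metadata = metadata)
}

.gbLocation <- function(start, end, strand) {
  loc <- sprintf("%d..%d", start + 1L, end)
  if (strand == "-") loc <- sprintf("complement(%s)", loc)
  loc
}

.gbWrapQualifier <- function(key, value) {
  text <- sprintf("/%s=\"%s\"", key, gsub("\"", "'", value))
  width <- 58L
  out <- character(0)
  while (nchar(text) > width) {
    cutAt <- max(gregexpr(" ", substr(text, 1, width))[[1]])
    if (cutAt <= 1L) break  # unbreakable token: emit long line
    out <- c(out, substr(text, 1, cutAt - 1L))
    text <- substr(text, cutAt + 1L, nchar(text))
  }
  c(out, text)
}

.gbRecordLines <- function(map) {
  stopifnot(is(map, "AssemblyMap"))
  methods::validObject(map)
  n <- nchar(map@sequence)
  lines <- c(
    sprintf("LOCUS       %-17s %d bp    DNA     %-8s SYN %s",
            gsub("\\s+", "_", map@name), n, map@topology, .GB_DATE),
    sprintf("DEFINITION  %s.", map@name),
    "ACCESSION   .",
    "VERSION     .",
    "KEYWORDS    .",
    "SOURCE      synthetic DNA construct",
    "  ORGANISM  synthetic DNA construct")
  for (p in map@provenance)
    lines <- c(lines, sprintf("COMMENT     %s", p))
  lines <- c(lines, "FEATURES             Location/Qualifiers")
  ft <- map@features
  for (i in seq_len(nrow(ft))) {
    lines <- c(lines, sprintf("     %-16s%s", ft$type[i],
                              .gbLocation(ft$start[i], ft$end[i],
                                          ft$strand[i])))
    quals <- .gbWrapQualifier("label", ft$label[i])
    if (nzchar(ft$note[i]))
      quals <- c(quals, .gbWrapQualifier("note", ft$note[i]))
    lines <- c(lines, paste0(strrep(" ", 21L), quals))
  }
  lines <- c(lines, "ORIGIN")
  s <- tolower(map@sequence)
  for (off in seq.int(1L, n, by = 60L)) {
    chunk <- substr(s, off, min(off + 59L, n))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", off, paste(groups, collapse = " ")))
  }
  c(lines, "//")
}

#' Write AssemblyMap records to a GenBank flat file
#'
#' Every feature carries an Ape-style `/label` qualifier (plus `/note`
#' when set); map provenance notes become COMMENT lines; topology is
#' recorded on the LOCUS line. Multiple maps produce a multi-record file.
#' Output is byte-deterministic.
#'
#' @param map An [AssemblyMap-class] or a list of them.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeGenbank <- function(map, path) {
  maps <- if (is(map, "AssemblyMap")) list(map) else map
  stopifnot(length(maps) >= 1L,
            all(vapply(maps, function(m) is(m, "AssemblyMap"), logical(1))))
  lines <- unlist(lapply(maps, .gbRecordLines), use.names = FALSE)
  con <- file(path, open = "wb")  # fixed LF endings for byte determinism
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

.gbParseLocation <- function(loc, lineno, path) {
  strand <- "+"
  if (grepl("^complement\\(.*\\)$", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^\\d+\\.\\.\\d+$", loc)) {
    parts <- as.integer(strsplit(loc, "\\.\\.")[[1]])
  } else if (grepl("^\\d+$", loc)) {
    parts <- rep(as.integer(loc), 2L)
  } else {
    .formatError("unsupported feature location '%s' at line %d of '%s'",
                 loc, lineno, path)
  }
  list(start = parts[1] - 1L, end = parts[2], strand = strand)
}

#' Read a GenBank flat file
#'
#' Parses LOCUS (name, length, topology), COMMENT lines (provenance),
#' the feature table (simple and `complement()` locations; `/label` and
#' `/note` qualifiers, wrapped lines rejoined) and the ORIGIN sequence.
#' Parse failures name the offending line.
#'
#' @param path Path to a `.gb` file.
#' @return A single [AssemblyMap-class], or a list of them for a
#'   multi-record file.
#' @export
readGenbank <- function(path) {
  if (!file.exists(path)) .formatError("GenBank file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    while (i <= n && !startsWith(lines[i], "LOCUS")) {
      if (nzchar(trimws(lines[i])))
        .formatError("expected LOCUS at line %d of '%s'", i, path)
      i <- i + 1L
    }
    if (i > n) break
    parsed <- .gbParseRecord(lines, i, path)
    recs[[length(recs) + 1L]] <- parsed$map
    i <- parsed$nextLine
  }
  if (length(recs) == 0L) .formatError("no GenBank records in '%s'", path)
  if (length(recs) == 1L) recs[[1]] else recs
}

.gbParseRecord <- function(lines, i, path) {
  locus <- strsplit(trimws(lines[i]), "\\s+")[[1]]
  if (length(locus) < 3L)
    .formatError("malformed LOCUS at line %d of '%s'", i, path)
  name <- locus[2]
  declaredLen <- suppressWarnings(as.integer(locus[3]))
  topology <- if ("circular" %in% locus) "circular" else "linear"
  provenance <- character(0)
  feats <- list()
  seqchunks <- character(0)
  i <- i + 1L
  n <- length(lines)
  state <- "header"
  curFeat <- NULL
  curQual <- NULL   # c(key, value) being accumulated
  flushQual <- function() {
    if (is.null(curQual) || is.null(curFeat)) return()
    key <- curQual[[1]]; val <- curQual[[2]]
    if (key == "label") curFeat$label <<- val
    else if (key == "note") curFeat$note <<- val
    curQual <<- NULL
  }
  flushFeat <- function() {
    flushQual()
    if (!is.null(curFeat)) {
      feats[[length(feats) + 1L]] <<- curFeat
      curFeat <<- NULL
    }
  }
  while (i <= n) {
    ln <- lines[i]
    if (startsWith(ln, "//")) { i <- i + 1L; break }
    if (startsWith(ln, "FEATURES")) {
      state <- "features"; i <- i + 1L; next
    }
    if (startsWith(ln, "ORIGIN")) {
      flushFeat(); state <- "origin"; i <- i + 1L; next
    }
    if (state == "header") {
      if (startsWith(ln, "COMMENT"))
        provenance <- c(provenance, sub("^COMMENT\\s{0,5}", "", ln))
      i <- i + 1L; next
    }
    if (state == "features") {
      body <- substring(ln, 6L)
      if (grepl("^\\S", body)) {           # new feature line
        flushFeat()
        toks <- strsplit(trimws(body), "\\s+")[[1]]
        if (length(toks) != 2L)
          .formatError("malformed feature line %d of '%s'", i, path)
        loc <- .gbParseLocation(toks[2], i, path)
        curFeat <- data.frame(start = loc$start, end = loc$end,
                              strand = loc$strand, type = toks[1],
                              label = "", note = "",
                              stringsAsFactors = FALSE)
      } else {
        qtext <- trimws(ln)
        if (startsWith(qtext, "/")) {
          flushQual()
          m <- regmatches(qtext, regexec('^/([A-Za-z_]+)="?(.*?)"?$', qtext))[[1]]
          if (length(m) != 3L)
            .formatError("malformed qualifier at line %d of '%s'", i, path)
          curQual <- list(m[2], m[3])
        } else if (!is.null(curQual)) {    # wrapped continuation
          curQual[[2]] <- paste(curQual[[2]], sub('"$', "", qtext))
        } else {
          .formatError("unexpected feature-table line %d of '%s'", i, path)
        }
      }
      i <- i + 1L; next
    }
    if (state == "origin") {
      chunk <- gsub("[^A-Za-z]", "", ln)
      seqchunks <- c(seqchunks, chunk)
      i <- i + 1L; next
    }
    i <- i + 1L
  }
  sequence <- toupper(paste(seqchunks, collapse = ""))
  if (!is.na(declaredLen) && nchar(sequence) != declaredLen)
    .formatError("sequence length %d disagrees with LOCUS (%d) in '%s'",
                 nchar(sequence), declaredLen, path)
  features <- if (length(feats) > 0L) do.call(rbind, feats) else
    .emptyFeatures()
  rownames(features) <- NULL
  map <- assemblyMap(name = name, sequence = sequence, topology = topology,
                     features = features, provenance = provenance)
  list(map = map, nextLine = i)
}
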