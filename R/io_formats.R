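#' Structure-annotated alignment
#'
#' Container for a gapped multiple alignment of RNA sequences together with a
#' consensus secondary structure in dot-bracket notation.  This is the unit
#' that gets scored: typically one structural-alignment block with the shared
#' structure proposed by a motif-discovery tool.
#'
#' Sequences are upper-case RNA over `A C G U N -` (DNA `T` is converted to
#' `U` on construction); the structure string has the same length as every
#' row, its brackets are balanced and non-crossing, and every base pair spans
#' more than `h` columns (minimum hairpin size).
#'
#' @param rows named character vector of aligned sequences (names are species
#'   / row identifiers and must be unique).
#' @param structure dot-bracket string of the consensus structure.
#' @param id alignment identifier.
#' @param h minimum hairpin size used to validate the structure (default 3).
#' @return An object of class `crs_alignment` with elements `rows`,
#'   `structure`, `id` and `L` (alignment length).
#' @examples
#' aln <- crs_alignment(c(human = "GGGAAACCC", mouse = "GGGAAACCC"),
#'                      "(((...)))")
#' alignment_stats(aln)
#' @export
crs_alignment <- function(rows, structure, id = "aln", h = 3) {
  if (length(rows) < 1L) stop("alignment needs at least one row")
  if (is.null(names(rows)) || anyNA(names(rows)) || any(names(rows) == ""))
    stop("alignment rows must be named")
  if (anyDuplicated(names(rows))) stop("duplicate row names in alignment")
  rows <- vapply(rows, normalize_rna, character(1))
  L <- unique(nchar(rows))
  if (length(L) != 1L)
    stop("parse error: unequal row lengths (", paste(sort(L), collapse = ", "), ")")
  structure <- normalize_structure(structure)
  if (nchar(structure) != L)
    stop("structure length ", nchar(structure), " != alignment length ", L)
  parse_structure(structure, h = h)  # validates balance / crossing / span
  bad <- grepl("[^ACGUN-]", rows)
  if (any(bad))
    stop("invalid characters in rows: ", paste(names(rows)[bad], collapse = ", "))
  obj <- list(rows = rows, structure = structure, id = id, L = L)
  class(obj) <- "crs_alignment"
  obj
}

#' @export
print.crs_alignment <- function(x, ...) {
  cat(sprintf("<crs_alignment '%s'> %d rows x %d columns, %d base pairs\n",
              x$id, length(x$rows), x$L,
              nrow(parse_structure(x$structure)$pairs)))
  invisible(x)
}

normalize_rna <- function(s) {
  s <- toupper(s)
  s <- gsub("T", "U", s, fixed = TRUE)
  s <- gsub("[.~_]", "-", s)
  s <- gsub("[^ACGU-]", "N", s)
  s
}

# WUSS and friends -> plain ()/.
normalize_structure <- function(s) {
  ch <- strsplit(s, "")[[1]]
  open <- ch %in% c("(", "<", "[", "{")
  close <- ch %in% c(")", ">", "]", "}")
  letters_pk <- grepl("[A-Za-z]", ch)
  if (any(letters_pk))
    warning("pseudoknot letters in structure treated as unpaired")
  out <- rep(".", length(ch))
  out[open] <- "("
  out[close] <- ")"
  paste(out, collapse = "")
}

#' Read a Stockholm alignment with consensus structure
#'
#' Parses a (possibly interleaved) Stockholm file holding one alignment and a
#' `#=GC SS_cons` consensus-structure line.  WUSS bracket symbols are
#' normalized to `(`/`)`/`.`, `T` to `U`, and sequences are upper-cased.
#'
#' @param path file path.
#' @param h minimum hairpin size for structure validation.
#' @return A [crs_alignment].
#' @export
read_stockholm <- function(path, h = 3) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  seqs <- character(0)
  ss <- ""
  for (ln in lines) {
    if (grepl("^# STOCKHOLM", ln) || ln == "//") next
    if (grepl("^#=GC\\s+SS_cons\\s", ln)) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      ss <- paste0(ss, parts[length(parts)])
    } else if (startsWith(ln, "#")) {
      next
    } else {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(parts) != 2L) stop("parse error: malformed sequence line: ", ln)
      nm <- parts[1]
      seqs[nm] <- paste0(if (nm %in% names(seqs)) seqs[nm] else "", parts[2])
    }
  }
  if (length(seqs) == 0L) stop("no sequences found in ", path)
  if (!nzchar(ss)) stop("no #=GC SS_cons line found in ", path)
  crs_alignment(seqs, ss, id = sub("\\.[^.]*$", "", basename(path)), h = h)
}

#' Write a Stockholm alignment
#'
#' @param aln a [crs_alignment].
#' @param path output file path.
#' @export
write_stockholm <- function(aln, path) {
  w <- max(nchar(names(aln$rows)), nchar("#=GC SS_cons"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  writeLines(sprintf("%-*s %s", w, names(aln$rows), aln$rows), con)
  writeLines(sprintf("%-*s %s", w, "#=GC SS_cons", aln$structure), con)
  writeLines("//", con)
  invisible(path)
}

#' Read a Newick tree with branch lengths
#'
#' Thin validating wrapper around [ape::read.tree()]: requires a rooted or
#' unrooted tree whose every edge carries a finite non-negative branch length
#' (expected substitutions per site) and whose leaf names are unique.
#'
#' @param path file path, or a Newick string via `text`.
#' @param text optional Newick string (used instead of `path`).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick input")
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree")
  if (anyDuplicated(tree$tip.label))
    stop("leaf name collision: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge)) {
    miss <- if (is.null(tree$edge.length)) tree$tip.label[1] else "some edge"
    stop("missing branch length for ", miss)
  }
  if (anyNA(tree$edge.length))
    stop("missing branch length for ",
         paste(na_edge_tips(tree), collapse = ", "))
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  invisible(tree)
}

na_edge_tips <- function(tree) {
  bad <- which(is.na(tree$edge.length))
  kids <- tree$edge[bad, 2]
  ifelse(kids <= length(tree$tip.label), tree$tip.label[kids], "internal node")
}

#' Genomic interval sets (BED3-BED6)
#'
#' An `interval_set` is a data frame with columns `chrom`, `start`, `end`
#' (0-based half-open), `name`, `score`, `strand` (`+`, `-` or `.`).
#'
#' @param chrom,start,end,name,score,strand vectors, recycled to a common
#'   length.
#' @return A data frame of class `interval_set`.
#' @export
interval_set <- function(chrom = character(0), start = integer(0),
                         end = integer(0), name = ".", score = 0,
                         strand = ".") {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), name = rep_len(as.character(name), n),
                   score = rep_len(as.numeric(score), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) in record ", bad[1])
  if (any(!df$strand %in% c("+", "-", ".")))
    stop("strand must be one of + - .")
  class(df) <- c("interval_set", "data.frame")
  df
}

#' Read / write BED files
#'
#' `read_bed()` accepts the BED3-BED6 dialect; missing name/score/strand
#' columns are filled with `"."`, `0`, `"."`.  `write_bed()` writes
#' tab-separated BED6 (or BED3 when all name/score/strand are defaults), so
#' that `write_bed(read_bed(f))` round-trips canonical records.
#'
#' @param path file path.
#' @return An [interval_set].
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) return(interval_set())
  parts <- strsplit(lines, "\t| +")
  ncols <- lengths(parts)
  if (any(ncols < 3L))
    stop("BED parse error at line ", which(ncols < 3L)[1], ": need >= 3 fields")
  get <- function(i, default) vapply(parts, function(p)
    if (length(p) >= i) p[i] else default, character(1))
  start <- suppressWarnings(as.integer(get(2, NA)))
  end <- suppressWarnings(as.integer(get(3, NA)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop("BED record error at line ", bad[1], ": need 0 <= start < end")
  interval_set(chrom = get(1, "."), start = start, end = end,
               name = get(4, "."),
               score = suppressWarnings(as.numeric(get(5, "0"))),
               strand = get(6, "."))
}

#' @rdname read_bed
#' @param set an [interval_set] to write.
#' @export
write_bed <- function(set, path) {
  bed3 <- all(set$name == ".") && all(set$score == 0) && all(set$strand == ".")
  cols <- if (bed3) set[, c("chrom", "start", "end")] else
    set[, c("chrom", "start", "end", "name", "score", "strand")]
  write.table(cols, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge overlapping intervals
#'
#' Collapses strictly overlapping intervals (strand ignored) into maximal
#' unions, e.g. to turn individual CRS predictions into CRS regions.  Abutting
#' half-open intervals (`[0,10)`, `[10,20)`) do not overlap and are kept
#' separate.  Output is sorted and disjoint; merging is idempotent.
#'
#' @param set an [interval_set].
#' @return An [interval_set] of merged intervals (name `.`/score 0/strand `.`).
#' @export
merge_intervals <- function(set) {
  if (nrow(set) == 0L) return(interval_set())
  out <- lapply(split(seq_len(nrow(set)), set$chrom), function(idx) {
    ir <- IRanges::IRanges(start = set$start[idx] + 1L, end = set$end[idx])
    # min.gapwidth = 0 keeps abutting intervals apart (strict overlap only)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    data.frame(chrom = set$chrom[idx[1]],
               start = IRanges::start(red) - 1L, end = IRanges::end(red))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  interval_set(out$chrom, out$start, out$end)
}

#' Per-alignment summary statistics
#'
#' GC content over all non-gap characters and average pairwise sequence
#' identity (SI).  SI uses the gap-included denominator: for each row pair the
#' number of columns where both rows carry the same non-gap character is
#' divided by the full alignment length; a column gapped in either row counts
#' as a mismatch.  For a single-row alignment SI is reported as 1 with a
#' warning (no pairs to compare).
#'
#' @param aln a [crs_alignment].
#' @return A list with `gc`, `si`, `length`, `n_species`.
#' @export
alignment_stats <- function(aln) {
  mat <- do.call(rbind, strsplit(aln$rows, ""))
  chars <- mat[mat != "-"]
  gc <- if (length(chars)) mean(chars %in% c("G", "C")) else NA_real_
  n <- nrow(mat)
  if (n == 1L) {
    warning("single-row alignment: SI reported as 1 by convention")
    si <- 1
  } else {
    tot <- 0
    npair <- 0L
    for (a in seq_len(n - 1L)) for (b in seq((a + 1L), n)) {
      same <- mat[a, ] == mat[b, ] & mat[a, ] != "-"
      tot <- tot + sum(same) / aln$L
      npair <- npair + 1L
    }
    si <- tot / npair
  }
  list(gc = gc, si = si, length = aln$L, n_species = n)
}

#' Filter alignment blocks by length and species composition
#'
#' Keeps blocks of alignment length at least `min_len` that contain the
#' anchor species and at least `min_nonprimates` rows classified as
#' non-primate.  This is the input filter applied to genome-alignment blocks
#' before structural realignment.
#'
#' @param blocks list of [crs_alignment] objects.
#' @param species_class named character vector mapping row names to
#'   `"primate"` or `"nonprimate"`; must cover every row name encountered.
#' @param anchor anchor species name (must be present in kept blocks).
#' @param min_len minimum alignment length (default 60).
#' @param min_nonprimates minimum number of non-primate rows (default 3).
#' @return The kept sublist of `blocks`.
#' @export
filter_alignment_blocks <- function(blocks, species_class, anchor,
                                    min_len = 60, min_nonprimates = 3) {
  if (!all(species_class %in% c("primate", "nonprimate")))
    stop("species_class values must be 'primate' or 'nonprimate'")
  keep <- vapply(blocks, function(b) {
    nm <- names(b$rows)
    unknown <- setdiff(nm, names(species_class))
    if (length(unknown))
      stop("unknown species name: ", paste(unknown, collapse = ", "))
    b$L >= min_len && anchor %in% nm &&
      sum(species_class[nm] == "nonprimate") >= min_nonprimates
  }, logical(1))
  blocks[keep]
}

#' Annotate fixed-width genome windows with GC and SI
#'
#' Helper constructing the window grid used by [stratified_enrichment()]:
#' fixed-width windows with per-window GC content and sequence identity.
#'
#' @param chrom,start,end,gc,si vectors of equal length; `gc` and `si` in
#'   `[0, 1]`; window width must be constant.
#' @return A data frame of class `genome_windows`.
#' @export
genome_windows <- function(chrom, start, end, gc, si) {
  w <- unique(end - start)
  if (length(w) != 1L) stop("window width must be constant")
  if (any(gc < 0 | gc > 1) || any(si < 0 | si > 1))
    stop("gc and si must lie in [0, 1]")
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), gc = gc, si = si,
                   stringsAsFactors = FALSE)
  class(df) <- c("genome_windows", "data.frame")
  df
}
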