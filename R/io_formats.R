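#' Read a genome FASTA
#'
#' Loads a genome into a light container holding the sequences (uppercased)
#' and an index of chromosome names and lengths. All internal coordinates in
#' this package are 0-based half-open; conversions to the 1-based file
#' conventions (CX report, GFF3) happen only at file boundaries.
#'
#' @param path FASTA file.
#' @return an object of class `rddm_genome`: list with `index`
#'   (data.table: chrom, length) and `seqs` (named `DNAStringSet`).
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) .stopf("empty FASTA: %s", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) .stopf("duplicate FASTA header in %s", path)
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(seqs) <- nm
  genome_from_seqs(seqs)
}

#' Build a genome container from sequences
#'
#' @param seqs named `DNAStringSet` (or named character vector).
#' @return `rddm_genome` object, see [read_genome_fasta()].
#' @export
genome_from_seqs <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    .stopf("sequences must be named")
  idx <- data.table(chrom = names(seqs),
                    length = BiocGenerics::width(seqs))
  if (any(idx$length <= 0L)) .stopf("zero-length sequence")
  structure(list(index = idx, seqs = seqs), class = "rddm_genome")
}

#' @export
print.rddm_genome <- function(x, ...) {
  cat(sprintf("<rddm_genome> %d sequence(s), %s bp total\n",
              nrow(x$index), format(sum(as.numeric(x$index$length)),
                                    big.mark = ",")))
  invisible(x)
}

#' Write a genome FASTA
#' @param genome `rddm_genome`.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seqs, path, width = 70L)
  invisible(path)
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Derive cytosine contexts from genome sequence
#'
#' Classifies every cytosine on both strands into CG, CHG or CHH
#' (H = A, C or T). A cytosine followed immediately by G is CG and needs
#' only two bases, so a terminal CG dinucleotide is still classified; other
#' contexts need the full trinucleotide and cytosines that cannot complete
#' one are skipped, as are trinucleotides containing N or other ambiguity
#' codes (their count is recorded in the `n_skipped` attribute).
#' Minus-strand cytosines are read 5'->3' on the reverse complement;
#' positions always refer to the forward strand (0-based).
#'
#' @param genome `rddm_genome` object.
#' @return data.table (chrom, pos, strand, context, tri), sorted by
#'   chromosome and position. `tri` is the trinucleotide as read on the
#'   cytosine's own strand, padded with N when truncated at a contig end.
#' @export
derive_contexts <- function(genome) {
  out <- vector("list", nrow(genome$index))
  skipped <- 0L
  for (i in seq_len(nrow(genome$index))) {
    chromi <- genome$index$chrom[i]
    ch <- strsplit(as.character(genome$seqs[[i]]), "", fixed = TRUE)[[1]]
    L <- length(ch)

    # plus strand: cytosine at p, trinucleotide ch[p..p+2]
    cp <- which(ch == "C")
    cp <- cp[cp < L]                       # need at least one downstream base
    h1 <- ch[cp + 1L]
    h2 <- rep(NA_character_, length(cp))
    ok2 <- cp + 2L <= L
    h2[ok2] <- ch[cp[ok2] + 2L]
    ctx_p <- rep(NA_character_, length(cp))
    ctx_p[h1 == "G"] <- "CG"
    needs3 <- h1 %in% c("A", "C", "T")
    ok3 <- needs3 & !is.na(h2) & h2 %in% c("A", "C", "G", "T")
    ctx_p[ok3 & h2 == "G"] <- "CHG"
    ctx_p[ok3 & h2 != "G"] <- "CHH"
    skipped <- skipped + sum(is.na(ctx_p) & !(needs3 & is.na(h2))) +
      sum(needs3 & is.na(h2))
    tri_p <- paste0("C", h1, ifelse(is.na(h2), "N", h2))
    keep <- !is.na(ctx_p)
    plus <- data.table(chrom = chromi, pos = cp[keep] - 1L, strand = "+",
                       context = ctx_p[keep], tri = tri_p[keep])

    # minus strand: cytosine where the forward base is G at p; the
    # trinucleotide on the minus strand is comp(ch[p]), comp(ch[p-1]),
    # comp(ch[p-2])
    gp <- which(ch == "G")
    gp <- gp[gp > 1L]
    m1 <- ch[gp - 1L]                      # complement gives the H1 base
    m2 <- rep(NA_character_, length(gp))
    okm <- gp - 2L >= 1L                   # zero indices must not be
    m2[okm] <- ch[gp[okm] - 2L]            # subsetted (they drop elements)
    h1m <- unname(.COMP[m1])
    h2m <- unname(.COMP[m2])
    ctx_m <- rep(NA_character_, length(gp))
    ctx_m[!is.na(h1m) & h1m == "G"] <- "CG"
    needs3m <- !is.na(h1m) & h1m %in% c("A", "C", "T")
    ok3m <- needs3m & !is.na(h2m)
    ctx_m[ok3m & h2m == "G"] <- "CHG"
    ctx_m[ok3m & h2m != "G"] <- "CHH"
    skipped <- skipped + sum(is.na(ctx_m))
    tri_m <- paste0("C", ifelse(is.na(h1m), "N", h1m),
                    ifelse(is.na(h2m), "N", h2m))
    keepm <- !is.na(ctx_m)
    minus <- data.table(chrom = chromi, pos = gp[keepm] - 1L, strand = "-",
                        context = ctx_m[keepm], tri = tri_m[keepm])
    out[[i]] <- rbind(plus, minus)
  }
  res <- rbindlist(out)
  setorder(res, chrom, pos, strand)
  setattr(res, "n_skipped", skipped)
  res[]
}

#' Read a Bismark-style CX cytosine report
#'
#' Tab-separated, 7 columns: chrom, 1-based position, strand, methylated
#' count, unmethylated count, context, trinucleotide. Positions are
#' converted to the package-internal 0-based convention. Zero-coverage
#' rows are retained.
#'
#' @param path report file.
#' @param genome optional `rddm_genome` used to validate positions.
#' @return data.table (chrom, pos, strand, context, meth, unmeth, tri).
#' @export
read_cx_report <- function(path, genome = NULL) {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "pos", "strand", "meth", "unmeth",
                            "context", "tri"),
              colClasses = list(character = c(1, 3, 6, 7),
                                integer = c(2, 4, 5)))
  if (nrow(dt) == 0L) .stopf("empty CX report: %s", path)
  bad_ctx <- setdiff(unique(dt$context), c("CG", "CHG", "CHH"))
  if (length(bad_ctx))
    .stopf("unknown context token(s) in %s: %s", path,
           paste(bad_ctx, collapse = ", "))
  if (!all(dt$strand %in% c("+", "-")))
    .stopf("invalid strand in %s", path)
  .check_count(dt$meth, "meth counts")
  .check_count(dt$unmeth, "unmeth counts")
  dt[, pos := pos - 1L]
  if (!is.null(genome)) {
    len <- setNames(genome$index$length, genome$index$chrom)
    if (!all(dt$chrom %in% names(len)))
      .stopf("CX report chromosome not in genome")
    if (dt[, any(pos < 0L | pos >= len[chrom])])
      .stopf("CX report position out of chromosome range")
  }
  setorder(dt, chrom, pos, strand)
  dt[]
}

#' Write a CX cytosine report
#'
#' Inverse of [read_cx_report()]: emits 1-based positions, tab-separated,
#' no header, sorted by chromosome and position.
#'
#' @param records data.table with chrom, pos (0-based), strand, context,
#'   meth, unmeth and optionally tri.
#' @param path output file.
#' @export
write_cx_report <- function(records, path) {
  dt <- as.data.table(records)
  if (!"tri" %in% names(dt)) dt[, tri := context]
  out <- dt[, .(chrom, pos = pos + 1L, strand, meth, unmeth, context, tri)]
  setorder(out, chrom, pos, strand)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene/TE features from GFF3 or BED
#'
#' GFF3 (1-based closed) is parsed with `rtracklayer::import` and converted
#' to 0-based half-open coordinates; feature kind is taken from the GFF type
#' (`gene` -> "gene"; `transposable_element`, `transposon`,
#' `transposable_element_gene` -> "TE"; other types are dropped).
#' BED input (native 0-based half-open) uses the name field as the id and
#' expects the kind encoded as a `kind|id` name (plain names default to
#' kind "gene").
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED file.
#' @return data.table (chrom, start, end, strand, kind, id).
#' @export
read_features <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    type <- as.character(gr$type)
    kind <- rep(NA_character_, length(gr))
    kind[type == "gene"] <- "gene"
    kind[type %in% c("transposable_element", "transposon",
                     "transposable_element_gene")] <- "TE"
    keep <- !is.na(kind)
    gr <- gr[keep]
    id <- gr$ID
    if (is.null(id)) id <- gr$Name
    if (is.null(id)) id <- paste0("feat", seq_along(gr))
    dt <- data.table(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = BiocGenerics::start(gr) - 1L,
      end = BiocGenerics::end(gr),
      strand = sub("\\*", ".", as.character(BiocGenerics::strand(gr))),
      kind = kind[keep], id = as.character(id))
  } else {
    dt <- fread(path, header = FALSE)
    setnames(dt, seq_len(min(6, ncol(dt))),
             c("chrom", "start", "end", "name", "score", "strand")[
               seq_len(min(6, ncol(dt)))])
    if (!"name" %in% names(dt)) dt[, name := paste0("feat", .I)]
    if (!"strand" %in% names(dt)) dt[, strand := "."]
    kindid <- data.table::tstrsplit(dt$name, "|", fixed = TRUE)
    if (length(kindid) >= 2) {
      dt[, kind := kindid[[1]]][, id := kindid[[2]]]
    } else {
      dt[, kind := "gene"][, id := name]
    }
    dt <- dt[, .(chrom, start, end, strand, kind, id)]
  }
  if (nrow(dt) && any(dt$end <= dt$start))
    .stopf("feature with end <= start in %s", path)
  setorder(dt, chrom, start, end)
  dt[]
}

#' Write features as GFF3
#'
#' @param features data.table (chrom, start, end, strand, kind, id),
#'   0-based half-open.
#' @param path output file.
#' @export
write_features_gff3 <- function(features, path) {
  dt <- as.data.table(features)
  type <- fifelse(dt$kind == "TE", "transposable_element", dt$kind)
  lines <- sprintf("%s\trddmr\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                   dt$chrom, type, dt$start + 1L, dt$end,
                   fifelse(dt$strand %in% c("+", "-"), dt$strand, "."),
                   dt$id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a chromatin-state BED
#'
#' BED4 with the state (1-9, optionally written `state8`) in the name
#' column. Segments must be non-overlapping within each chromosome.
#'
#' @param path BED file.
#' @return data.table (chrom, start, end, state).
#' @export
read_states_bed <- function(path) {
  dt <- fread(path, header = FALSE,
              col.names = c("chrom", "start", "end", "name")[1:4])
  st <- as.integer(sub("^state", "", dt$name))
  if (any(is.na(st)) || any(st < 1L | st > 9L))
    .stopf("chromatin state outside 1..9 in %s", path)
  dt[, state := st][, name := NULL]
  if (any(dt$end <= dt$start)) .stopf("state segment with end <= start")
  setorder(dt, chrom, start)
  if (dt[, any(start < shift(end, fill = -1L)), by = chrom][, any(V1)])
    .stopf("overlapping chromatin-state segments in %s", path)
  dt[]
}

#' Write a chromatin-state BED
#' @param states data.table (chrom, start, end, state).
#' @param path output file.
#' @export
write_states_bed <- function(states, path) {
  dt <- as.data.table(states)
  setorder(dt, chrom, start)
  fwrite(dt[, .(chrom, start, end, name = paste0("state", state))],
         path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write regions (DMRs/DSRs) as BED6
#'
#' Name is `direction.context` (or plain direction when no context column
#' exists), score is `-10 log10(q)` capped at 1000 and written with full
#' precision, strand is ".". Output is sorted, so writing is deterministic.
#'
#' @param regions data.table with chrom, start, end and optionally
#'   direction, context, q.
#' @param path output file.
#' @export
write_regions_bed <- function(regions, path) {
  dt <- as.data.table(regions)
  if (!"direction" %in% names(dt)) dt[, direction := "region"]
  nm <- if ("context" %in% names(dt))
    paste(dt$direction, dt$context, sep = ".") else dt$direction
  qv <- if ("min_q" %in% names(dt)) dt$min_q else
    if ("q" %in% names(dt)) dt$q else rep(1, nrow(dt))
  score <- pmin(1000, -10 * log10(pmax(qv, 1e-300)))
  out <- data.table(chrom = dt$chrom, start = dt$start, end = dt$end,
                    name = nm, score = score, strand = ".")
  setorder(out, chrom, start, end, name)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED6 region file written by [write_regions_bed()]
#'
#' @param path BED file.
#' @return data.table (chrom, start, end, name, score, strand).
#' @export
read_regions_bed <- function(path) {
  dt <- fread(path, header = FALSE,
              col.names = c("chrom", "start", "end", "name", "score",
                            "strand"))
  if (nrow(dt) && any(dt$end <= dt$start))
    .stopf("region with end <= start in %s", path)
  setorder(dt, chrom, start, end, name)
  dt[]
}
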