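## Conservation inputs: ConSurf grades files, or an offline fallback from a
## multiple sequence alignment (normalized Shannon-entropy conservation with
## the ConSurf sign convention: negative = conserved).

#' Parse a ConSurf grades file
#'
#' Reads the tabular grades output (POS, SEQ, score, grade columns).  The
#' normalized score keeps the ConSurf sign convention, where negative values
#' represent highly conserved residues.
#'
#' @param path path to the grades file.
#' @param chain chain id to attach to the residue keys (default "A").
#' @return data.frame with `key`, `consurf_score`, `consurf_grade`.
#' @export
parse_consurf_grades <- function(path, chain = "A") {
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (ln in lines) {
    f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(f) < 4) next
    pos <- suppressWarnings(as.integer(f[1]))
    score <- suppressWarnings(as.numeric(f[3]))
    grade <- suppressWarnings(as.integer(gsub("[^0-9]", "", f[4])))
    if (is.na(pos) || is.na(score) || is.na(grade)) next
    if (grade < 1L || grade > 9L) next
    rows[[length(rows) + 1L]] <- data.frame(
      key = res_key(chain, pos, ""), consurf_score = score,
      consurf_grade = grade, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no parsable rows in ConSurf grades file: ", path)
  out
}

## read an aligned FASTA into a character matrix (rows = sequences)
read_alignment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("not a FASTA file: ", path)
  seqs <- character(length(hdr))
  names(seqs) <- sub("^>\\s*", "", lines[hdr])
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    seqs[i] <- toupper(gsub("[ \t]", "", paste(body, collapse = "")))
  }
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment rows have unequal lengths")
  do.call(rbind, strsplit(seqs, ""))
}

#' Conservation and homolog statistics from a multiple sequence alignment
#'
#' Offline fallback when no ConSurf file is available.  Per-column Shannon
#' entropy is rescaled to mean 0 / SD 1 over columns and sign-flipped so
#' that conserved columns score negative (ConSurf convention).  Also
#' reports, per column, the number of distinct amino acids among homologs
#' ("variant length") and whether any homolog carries a cysteine.
#'
#' @param msa_path aligned FASTA; the first sequence is the scored chain.
#' @param model a `structure_model`; ungapped positions of the first MSA row
#'   are mapped onto the model's residues of `chain` in order.
#' @param chain chain id to map onto (default "A").
#' @return data.frame with `key`, `msa_conservation`, `variant_length`,
#'   `cys_in_homologs`.
#' @export
compute_msa_conservation <- function(msa_path, model, chain = "A") {
  aln <- read_alignment(msa_path)
  ref <- aln[1, ]
  cols <- which(!ref %in% c("-", "."))
  res <- model$residues[model$residues$chain == chain, , drop = FALSE]
  if (length(cols) != nrow(res))
    stop(sprintf(paste0("ungapped MSA reference length (%d) does not match ",
                        "chain %s residue count (%d)"),
                 length(cols), chain, nrow(res)))
  ent <- numeric(length(cols))
  vlen <- integer(length(cols))
  cysh <- logical(length(cols))
  for (i in seq_along(cols)) {
    col <- aln[, cols[i]]
    col <- col[!col %in% c("-", ".", "X")]
    tab <- table(col)
    p <- tab / sum(tab)
    ent[i] <- -sum(p * log(p))
    vlen[i] <- length(tab)
    cysh[i] <- "C" %in% names(tab)
  }
  s <- if (stats::sd(ent) > 0) (ent - mean(ent)) / stats::sd(ent) else ent * 0
  ## low entropy = conserved = negative score
  data.frame(key = res$key, msa_conservation = s,
             variant_length = vlen, cys_in_homologs = cysh,
             stringsAsFactors = FALSE)
}
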