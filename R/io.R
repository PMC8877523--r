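#' Read / write plain-text sequence files
#'
#' One record per line: an optional `id<TAB>` prefix followed by the +/-1
#' charge string; `#` lines are comments. The writer and [parse_charges()]
#' round-trip exactly.
#'
#' @param path File path.
#' @return `read_sequences()`: a sequence tibble.
#' @export
read_sequences <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(sequence_tbl(character(0)))
  }
  parts <- strsplit(lines, "\t")
  has_id <- lengths(parts) >= 2L
  ids <- ifelse(has_id, vapply(parts, `[[`, "", 1L), NA_character_)
  strs <- vapply(parts, function(p) p[[length(p)]], "")
  if (anyNA(ids)) ids[is.na(ids)] <- paste0("s", which(is.na(ids)))
  sequence_tbl(stats::setNames(strs, ids))
}

#' @rdname read_sequences
#' @param sequences A sequence tibble.
#' @param header Optional `#` comment lines to prepend (provenance).
#' @export
write_sequences <- function(sequences, path, header = NULL) {
  lines <- character(0)
  if (!is.null(header)) lines <- paste0("# ", header)
  body <- vapply(seq_len(nrow(sequences)), function(j) {
    paste0(sequences$id[j], "\t", format_charges(sequences$seq[[j]]))
  }, "")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' Standard FASTA (single or multi-record) parsed with seqinr, reduced to
#' charge sequences with [reduce_protein()].
#'
#' @param path FASTA file.
#' @param mapping A [charge_mapping()].
#' @param favorable_sign Passed to [reduce_protein()].
#' @return A sequence tibble, one row per FASTA record.
#' @export
read_fasta_charges <- function(path, mapping = charge_mapping(),
                               favorable_sign = 1L) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE)
  seqs <- purrr::map(recs, function(r) {
    reduce_protein(toupper(as.character(r)), mapping, favorable_sign)
  })
  sequence_tbl(seqs, id = names(recs))
}

#' Write run outputs as TSV
#'
#' Tab-separated tables with `#` comment headers recording the package
#' version, the resolved configuration and the master seed, so every
#' output file documents how to regenerate itself.
#'
#' @param x A tibble (summary, events, histogram, ...).
#' @param path Output path.
#' @param config Optional [sim_config()] recorded in the header.
#' @export
write_tsv_output <- function(x, path, config = NULL) {
  hdr <- paste0("# patrans ",
                as.character(utils::packageVersion("patrans")))
  if (!is.null(config)) {
    hdr <- c(hdr, paste0("# direction=", config$direction, " tw=", config$tw,
                         " trials=", config$trials, " seed=", config$seed,
                         " V=", config$profile$V))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(utils::write.table(as.data.frame(x), con, sep = "\t",
                                      quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Generate the bundled reference inputs
#'
#' Writes the reference sequence panel, the default pore profile and small
#' seeded random/fixed-composition ensembles into a directory, in the
#' plain-text formats the readers in this package consume.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed for the random ensembles.
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(dir, seed = 1234567) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    reference = file.path(dir, "reference_sequences.txt"),
    profile = file.path(dir, "pore_profile.tsv"),
    random20 = file.path(dir, "random_N20.txt"),
    random40 = file.path(dir, "random_N40.txt")
  )
  write_sequences(reference_sequences(), paths["reference"],
                  header = "reference sequence panel (N=20 Q=8 blocks; IN reductions)")
  write_profile(pore_profile(), paths["profile"])
  write_sequences(sample_sequences(20, 200, seed), paths["random20"],
                  header = paste("random N=20 ensemble, seed", seed))
  write_sequences(sample_sequences(40, 100, seed + 1L), paths["random40"],
                  header = paste("random N=40 ensemble, seed", seed + 1L))
  for (Q in seq(0, 18, by = 2)) {
    p <- file.path(dir, sprintf("fixedQ_N20_Q%02d.txt", Q))
    write_sequences(sample_sequences(20, 50, seed + Q, Q = Q), p,
                    header = paste("fixed-composition N=20 ensemble, Q =", Q))
    paths[paste0("fixedQ", Q)] <- p
  }
  invisible(paths)
}
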