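#' @useDynLib cgphase, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Load a residue parameter table
#'
#' Reads a tab-separated table of per-residue bead parameters: one-letter
#' code, bead diameter sigma (nm), stickiness lambda (unitless, in
#' \[0,1\]), charge (elementary charges) and mass (g/mol).  The table must
#' contain exactly one row for each of the 20 canonical amino acids.
#'
#' @param source path to a TSV file (comment lines starting with `#` are
#'   skipped), or a `data.frame` with columns `code`, `sigma_nm`,
#'   `lambda`, `charge_e`, `mass_gmol`.
#' @param provenance free-text label recorded on the returned table.
#' @return a `param_table` object: a data.frame with columns `code`,
#'   `sigma`, `lambda`, `charge`, `mass`, rows named by code.
#' @examples
#' pt <- default_param_table()
#' pt["Y", "lambda"]
#' @export
load_parameter_table <- function(source, provenance = NULL) {
  if (is.character(source)) {
    if (!file.exists(source)) stop("parameter table file not found: ", source)
    df <- utils::read.delim(source, comment.char = "#",
                            stringsAsFactors = FALSE)
    if (is.null(provenance)) provenance <- basename(source)
  } else if (is.data.frame(source)) {
    df <- source
    if (is.null(provenance)) provenance <- "data.frame"
  } else {
    stop("source must be a file path or a data.frame")
  }
  need <- c("code", "sigma_nm", "lambda", "charge_e", "mass_gmol")
  if (!all(need %in% names(df)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  df$code <- as.character(df$code)

  bad <- which(!df$code %in% AA_CODES |
                 !is.finite(df$sigma_nm) | df$sigma_nm <= 0 |
                 !is.finite(df$lambda) | df$lambda < 0 | df$lambda > 1 |
                 !is.finite(df$charge_e) |
                 !is.finite(df$mass_gmol) | df$mass_gmol <= 0)
  if (length(bad))
    stop("malformed parameter row(s): ",
         paste(bad, collapse = ", "),
         " (code '", df$code[bad[1]], "')")
  dup <- unique(df$code[duplicated(df$code)])
  if (length(dup))
    stop("duplicate parameter rows for residue(s): ",
         paste(dup, collapse = ", "))
  missing <- setdiff(AA_CODES, df$code)
  if (length(missing))
    stop("parameter table incomplete; missing residue(s): ",
         paste(missing, collapse = ", "))

  out <- data.frame(code = df$code, sigma = df$sigma_nm, lambda = df$lambda,
                    charge = df$charge_e, mass = df$mass_gmol,
                    stringsAsFactors = FALSE)
  rownames(out) <- out$code
  out <- out[AA_CODES, ]
  attr(out, "provenance") <- provenance
  class(out) <- c("param_table", "data.frame")
  out
}

#' Packaged CALVADOS2-style default parameter table
#'
#' Returns the bead-parameter table shipped with the package (provenance
#' "CALVADOS2"): the stickiness scale optimized against experimental IDP
#' data by Tesei and co-workers, with standard residue diameters and
#' masses, Asp/Glu at -1 e, Arg/Lys at +1 e and His neutral.
#'
#' @return a `param_table`.
#' @export
default_param_table <- function() {
  path <- system.file("extdata", "calvados2_params.tsv", package = "cgphase")
  load_parameter_table(path, provenance = "CALVADOS2")
}

param_lookup <- function(table, codes) {
  stopifnot(inherits(table, "param_table"))
  unknown <- setdiff(unique(codes), rownames(table))
  if (length(unknown))
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "))
  table[codes, , drop = FALSE]
}

#' Combine bead parameters for a residue pair
#'
#' Pair diameter and stickiness are the arithmetic averages of the
#' residue-specific values, the combination rule of the underlying
#' hydropathy model.
#'
#' @param a,b one-letter residue codes.
#' @param table a `param_table`.
#' @return named numeric vector `c(sigma, lambda)` in nm / unitless.
#' @export
pair_params <- function(a, b, table) {
  pa <- param_lookup(table, a)
  pb <- param_lookup(table, b)
  c(sigma = (pa$sigma + pb$sigma) / 2,
    lambda = (pa$lambda + pb$lambda) / 2)
}

#' Construct a sequence record
#'
#' @param id record identifier.
#' @param residues character: either a single string or a vector of
#'   one-letter codes.
#' @param numbering_offset number of the first residue in the parent
#'   protein (1-based).
#' @return a `seq_record` list with elements `id`, `residues` (character
#'   vector) and `numbering_offset`.
#' @export
seq_record <- function(id, residues, numbering_offset = 1L) {
  if (length(residues) == 1L && nchar(residues[1]) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(as.character(residues))
  if (!length(residues)) stop("sequence must be non-empty")
  bad <- setdiff(unique(residues), AA_CODES)
  if (length(bad))
    stop("non-canonical residue code(s): ", paste(bad, collapse = ", "))
  structure(list(id = as.character(id), residues = residues,
                 numbering_offset = as.integer(numbering_offset)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("seq_record '%s': %d residues, numbering %d-%d\n", x$id,
              length(x$residues), x$numbering_offset,
              x$numbering_offset + length(x$residues) - 1L))
  invisible(x)
}

#' @export
length.seq_record <- function(x) length(x$residues)

#' Define a named region of a protein (1-based, inclusive)
#'
#' @param name region label.
#' @param start,end first and last residue numbers in parent-protein
#'   numbering.
#' @return a `region` list.
#' @export
region <- function(name, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (start > end) stop("region start must be <= end")
  structure(list(name = as.character(name), start = start, end = end),
            class = "region")
}

#' Standard MUT-16 / MUT-8 region definitions
#'
#' Convenience constructor for the disordered-region boundaries of the
#' C. elegans Mutator-focus scaffold MUT-16 and its client MUT-8: the
#' MUT-8-binding region (M8BR, 633-772), the foci-forming region (FFR,
#' 773-944 by default; the 945 endpoint reported in some contexts is
#' available via `ffr_end`), their union, and the MUT-8 N-terminal
#' prion-like domain (first 51 residues).
#'
#' @param ffr_end last residue of the FFR (944 or 945).
#' @return named list of `region` objects.
#' @export
mut16_regions <- function(ffr_end = 944) {
  list(M8BR = region("M8BR", 633, 772),
       FFR = region("FFR", 773, ffr_end),
       M8BR_FFR = region("M8BR+FFR", 633, ffr_end),
       MUT8_PLD = region("MUT8-PLD", 1, 51))
}

#' Extract a region from a sequence record
#'
#' @param seq a `seq_record`.
#' @param reg a `region` in the same (parent-protein) numbering.
#' @return a `seq_record` covering the region, with
#'   `numbering_offset = reg$start`.
#' @export
extract_region <- function(seq, reg) {
  stopifnot(inherits(seq, "seq_record"), inherits(reg, "region"))
  first <- seq$numbering_offset
  last <- first + length(seq$residues) - 1L
  if (reg$start < first || reg$end > last)
    stop(sprintf("region %d-%d out of range for sequence %d-%d",
                 reg$start, reg$end, first, last))
  idx <- (reg$start - first + 1L):(reg$end - first + 1L)
  seq_record(paste0(seq$id, "_", reg$name), seq$residues[idx],
             numbering_offset = reg$start)
}

#' Fraction of a sequence made of a residue set
#'
#' @param seq a `seq_record`.
#' @param residue_set character vector of one-letter codes; defaults to
#'   the aromatic set Phe/Tyr/Trp.
#' @return percentage (0-100).
#' @export
composition_fraction <- function(seq, residue_set = c("F", "Y", "W")) {
  stopifnot(inherits(seq, "seq_record"))
  if (!length(seq$residues)) stop("composition of empty sequence undefined")
  100 * sum(seq$residues %in% residue_set) / length(seq$residues)
}

#' Assign per-bead charges to a sequence
#'
#' Looks up side-chain charges from the parameter table, optionally adds
#' the terminal charges (+1 e on the first bead, -1 e on the last; for a
#' single-residue chain both land on the same bead) and sets His to a
#' configurable charge.
#'
#' @param seq a `seq_record`.
#' @param table a `param_table`.
#' @param termini_charged add +1/-1 e to the first/last bead (default
#'   TRUE).
#' @param his_charge charge assigned to His beads (default 0 e).
#' @return numeric vector of charges (e), one per residue.
#' @export
assign_charges <- function(seq, table, termini_charged = TRUE,
                           his_charge = 0) {
  p <- param_lookup(table, seq$residues)
  q <- p$charge
  q[seq$residues == "H"] <- his_charge
  if (termini_charged) {
    q[1] <- q[1] + 1
    q[length(q)] <- q[length(q)] - 1
  }
  q
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (single- or multi-record).
#' @return list of `seq_record` objects named by FASTA id.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::readAAStringSet(path)
    recs <- lapply(seq_along(aa), function(i) {
      id <- strsplit(names(aa)[i], "\\s+")[[1]][1]
      seq_record(id, as.character(aa[[i]]))
    })
  } else {
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    if (!length(hdr)) stop("no FASTA records in ", path)
    ends <- c(hdr[-1] - 1L, length(lines))
    recs <- lapply(seq_along(hdr), function(i) {
      id <- sub("^>\\s*(\\S+).*", "\\1", lines[hdr[i]])
      body <- paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
      seq_record(id, gsub("\\s", "", body))
    })
  }
  names(recs) <- vapply(recs, `[[`, "", "id")
  recs
}

#' Write sequence records to a FASTA file
#'
#' @param records a `seq_record` or list of them.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "seq_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$id), con)
    s <- paste(r$residues, collapse = "")
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
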