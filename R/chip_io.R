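#' Gene panel constructors
#'
#' A gene panel is the ordered set of assay identifiers measured on a chip.
#' Dynamic arrays run 48 assays against 48 samples, so the default panel has
#' 48 entries; any unique, non-empty set of names is accepted.
#'
#' @param assay_names Character vector of gene/assay identifiers.
#' @return A validated character vector of class `GenePanel`.
#' @export
gene_panel <- function(assay_names) {
  assay_names <- as.character(assay_names)
  if (length(assay_names) == 0L) {
    stop("a gene panel must contain at least one assay", call. = FALSE)
  }
  if (anyNA(assay_names) || any(!nzchar(assay_names))) {
    stop("gene panel names must be non-empty", call. = FALSE)
  }
  dup <- unique(assay_names[duplicated(assay_names)])
  if (length(dup) > 0L) {
    stop("duplicated assay names in panel: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  structure(assay_names, class = c("GenePanel", "character"))
}

#' @param n_genes Panel size (default 48, one dynamic-array assay bank).
#' @rdname gene_panel
#' @export
default_gene_panel <- function(n_genes = 48L) {
  n_genes <- .assert_count(n_genes, "n_genes")
  gene_panel(sprintf("G%02d", seq_len(n_genes)))
}

.canonical_passages <- c("fresh", "P0", "P1")

.check_passage <- function(passage) {
  passage <- as.character(passage)
  if (length(passage) != 1L || is.na(passage) || !nzchar(passage)) {
    stop("`passage` must be a single non-empty label", call. = FALSE)
  }
  if (!passage %in% .canonical_passages) {
    warning("non-canonical passage label '", passage,
            "' (canonical: ", paste(.canonical_passages, collapse = ", "),
            ")", call. = FALSE)
  }
  passage
}

# Construct a validated ChipRun from a numeric Ct matrix in which NA means
# "no amplification within the cycle limit". Numeric values at or above the
# limit are converted to the non-amplified state; non-positive values error.
new_chip_run <- function(chip_id, passage, ct, cycle_limit = 40L) {
  cycle_limit <- .assert_count(cycle_limit, "cycle_limit")
  stopifnot(is.matrix(ct), is.numeric(ct))
  if (is.null(rownames(ct)) || is.null(colnames(ct))) {
    stop("ChipRun Ct matrix needs cell rownames and gene colnames",
         call. = FALSE)
  }
  bad <- which(!is.na(ct) & ct <= 0)
  if (length(bad) > 0L) {
    stop("non-positive Ct values are invalid (first at flat index ",
         bad[[1L]], ")", call. = FALSE)
  }
  ct[!is.na(ct) & ct >= cycle_limit] <- NA_real_
  structure(
    list(chip_id = as.character(chip_id),
         passage = .check_passage(passage),
         cycle_limit = cycle_limit,
         ct = ct,
         cell_ids = rownames(ct),
         genes = colnames(ct)),
    class = "ChipRun"
  )
}

.long_columns <- c("chip_id", "cell_id", "gene", "ct", "call")

.parse_ct_field <- function(ct_chr, call_chr, path) {
  ct_chr <- trimws(ct_chr)
  call_chr <- trimws(call_chr)
  bad_call <- !call_chr %in% c("Pass", "Fail")
  if (any(bad_call)) {
    stop("invalid `call` value(s) in ", path, ": ",
         paste(unique(call_chr[bad_call]), collapse = ", "),
         " (expected Pass or Fail)", call. = FALSE)
  }
  ct <- suppressWarnings(as.numeric(ct_chr))
  not_num <- nzchar(ct_chr) & is.na(ct)
  if (any(not_num)) {
    stop("non-numeric ct value(s) in ", path, ": ",
         paste(unique(ct_chr[not_num]), collapse = ", "), call. = FALSE)
  }
  ct[call_chr == "Fail" | !nzchar(ct_chr)] <- NA_real_
  ct
}

#' Read one chip-level Ct export
#'
#' Two CSV dialects are accepted and auto-detected from the header line:
#' the long dialect with columns `chip_id,cell_id,gene,ct,call`
#' (`call` in `Pass`/`Fail`; `Fail` or an empty `ct` means the reaction did
#' not amplify), and the grid dialect with a leading `cell_id` column
#' followed by one column per gene (empty entries mean no amplification).
#' Any numeric Ct at or above `cycle_limit` is likewise stored as
#' non-amplified: a reaction that has not crossed threshold by the last
#' cycle is a non-expresser. Grid rows that are entirely empty (a failed
#' well) are dropped with a warning; partially empty rows are kept.
#'
#' @param path CSV file path.
#' @param panel [gene_panel()] the chip's genes must belong to.
#' @param passage Passage label for every cell on this chip
#'   (`fresh`, `P0`, `P1` are canonical; other labels warn).
#' @param cycle_limit Number of qPCR cycles run (default 40).
#' @param chip_id Chip identifier for the grid dialect (defaults to the file
#'   name); the long dialect carries its own.
#' @return A `ChipRun` object.
#' @export
read_chip_table <- function(path, panel, passage, cycle_limit = 40L,
                            chip_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  panel <- gene_panel(panel)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  header <- trimws(header)
  if (identical(header, .long_columns)) {
    df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
    .chip_run_from_long(df, panel, passage, cycle_limit, path)
  } else if (length(header) >= 2L && identical(header[[1L]], "cell_id")) {
    df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
    if (is.null(chip_id)) chip_id <- sub("\\.[^.]*$", "", basename(path))
    .chip_run_from_grid(df, panel, passage, cycle_limit, chip_id, path)
  } else {
    stop("malformed header in ", path, " at line 1: '",
         paste(header, collapse = ","),
         "' is neither the long dialect (chip_id,cell_id,gene,ct,call) ",
         "nor the grid dialect (cell_id,<genes...>)", call. = FALSE)
  }
}

.chip_run_from_long <- function(df, panel, passage, cycle_limit, path) {
  chip_ids <- unique(df$chip_id)
  if (length(chip_ids) != 1L) {
    stop("long-dialect file ", path, " must describe one chip, found: ",
         paste(chip_ids, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(df$gene), panel)
  if (length(unknown) > 0L) {
    stop("gene(s) not in panel in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  key <- paste(df$cell_id, df$gene, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate (cell, gene) pair in ", path, ": (",
         d$cell_id, ", ", d$gene, ")", call. = FALSE)
  }
  ct_val <- .parse_ct_field(df$ct, df$call, path)
  cells <- unique(df$cell_id)
  genes <- panel[panel %in% unique(df$gene)]
  ct <- matrix(NA_real_, length(cells), length(genes),
               dimnames = list(cells, genes))
  ct[cbind(match(df$cell_id, cells), match(df$gene, genes))] <- ct_val
  new_chip_run(chip_ids, passage, ct, cycle_limit)
}

.chip_run_from_grid <- function(df, panel, passage, cycle_limit, chip_id,
                                path) {
  genes_in_file <- colnames(df)[-1L]
  unknown <- setdiff(genes_in_file, panel)
  if (length(unknown) > 0L) {
    stop("gene(s) not in panel in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(genes_in_file)) {
    stop("duplicate gene column(s) in ", path, ": ",
         paste(unique(genes_in_file[duplicated(genes_in_file)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$cell_id)) {
    stop("duplicate cell_id row(s) in ", path, ": ",
         paste(unique(df$cell_id[duplicated(df$cell_id)]), collapse = ", "),
         call. = FALSE)
  }
  raw <- as.matrix(df[, -1L, drop = FALSE])
  blank <- apply(raw, 1L, function(r) all(!nzchar(trimws(r))))
  if (any(blank)) {
    warning("dropping ", sum(blank), " entirely blank cell row(s) in ",
            path, ": ", paste(df$cell_id[blank], collapse = ", "),
            call. = FALSE)
    raw <- raw[!blank, , drop = FALSE]
    df <- df[!blank, , drop = FALSE]
  }
  ct <- suppressWarnings(apply(raw, 2L, function(col) {
    col <- trimws(col)
    v <- as.numeric(col)
    bad <- nzchar(col) & is.na(v)
    if (any(bad)) {
      stop("non-numeric ct value(s) in ", path, ": ",
           paste(unique(col[bad]), collapse = ", "), call. = FALSE)
    }
    v
  }))
  ct <- matrix(ct, nrow = nrow(df),
               dimnames = list(df$cell_id, genes_in_file))
  ct <- ct[, panel[panel %in% genes_in_file], drop = FALSE]
  new_chip_run(chip_id, passage, ct, cycle_limit)
}

#' Merge chip runs into one cohort Ct matrix
#'
#' Stacks cells from several chips (typically one per passage group) into a
#' single cells x genes grid so that downstream normalization pools every
#' chip and passage. Cell identifiers are qualified by chip id to stay
#' unique; passage labels travel with each cell.
#'
#' @param runs List of `ChipRun` objects sharing the same gene set and
#'   cycle limit.
#' @return A `CtMatrix`: list with `ct` (cells x genes numeric matrix, NA =
#'   non-amplified), `cells` (data frame: `cell_id`, `passage`, `chip_id`,
#'   `well_id`), `genes`, `cycle_limit`.
#' @export
merge_runs <- function(runs) {
  if (inherits(runs, "ChipRun")) runs <- list(runs)
  stopifnot(length(runs) >= 1L,
            all(vapply(runs, inherits, logical(1L), "ChipRun")))
  ref <- runs[[1L]]
  for (r in runs[-1L]) {
    if (!setequal(r$genes, ref$genes)) {
      stop("chip runs measure different genes: ",
           paste(c(setdiff(r$genes, ref$genes),
                   setdiff(ref$genes, r$genes)), collapse = ", "),
           call. = FALSE)
    }
    if (r$cycle_limit != ref$cycle_limit) {
      stop("chip runs have different cycle limits (",
           ref$cycle_limit, " vs ", r$cycle_limit, ")", call. = FALSE)
    }
  }
  ct <- do.call(rbind, lapply(runs, function(r) {
    m <- r$ct[, ref$genes, drop = FALSE]
    rownames(m) <- paste(r$chip_id, rownames(m), sep = ".")
    m
  }))
  cells <- do.call(rbind, lapply(runs, function(r) {
    data.frame(cell_id = paste(r$chip_id, r$cell_ids, sep = "."),
               passage = r$passage,
               chip_id = r$chip_id,
               well_id = r$cell_ids,
               stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL
  if (anyDuplicated(cells$cell_id)) {
    stop("cell ids not unique after chip-id qualification: ",
         paste(unique(cells$cell_id[duplicated(cells$cell_id)]),
               collapse = ", "), call. = FALSE)
  }
  structure(
    list(ct = ct, cells = cells, genes = ref$genes,
         cycle_limit = ref$cycle_limit),
    class = "CtMatrix"
  )
}

#' Expresser / non-expresser mask
#'
#' A reaction counts as expressing only if it produced a numeric Ct strictly
#' below the cycle limit; a reaction still below threshold at the last cycle
#' never amplified.
#'
#' @param m A `CtMatrix`.
#' @return Logical cells x genes matrix, `TRUE` where the cell expresses the
#'   gene.
#' @export
expression_mask <- function(m) {
  stopifnot(inherits(m, "CtMatrix"))
  mask <- !is.na(m$ct) & m$ct < m$cycle_limit
  dimnames(mask) <- dimnames(m$ct)
  mask
}

#' Write / re-read a cohort in the long dialect
#'
#' `write_ct_long()` serializes a `CtMatrix` to the long CSV dialect
#' (`chip_id,cell_id,gene,ct,call`), writing non-amplified reactions as an
#' empty `ct` with `call=Fail`. `read_ct_long()` reads such a file back into
#' a `CtMatrix` given the passage label of each chip; the round trip is
#' bit-exact on Ct values and the non-amplified state.
#'
#' @param m A `CtMatrix`.
#' @param path Output CSV path.
#' @export
write_ct_long <- function(m, path) {
  stopifnot(inherits(m, "CtMatrix"))
  n_g <- length(m$genes)
  ct <- as.vector(t(m$ct))   # row-major: gene fastest
  df <- data.frame(
    chip_id = rep(m$cells$chip_id, each = n_g),
    cell_id = rep(m$cells$well_id, each = n_g),
    gene = rep(m$genes, times = nrow(m$ct)),
    ct = ifelse(is.na(ct), "", format(ct, digits = 17, trim = TRUE,
                                      scientific = FALSE)),
    call = ifelse(is.na(ct), "Fail", "Pass"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param path CSV path written by `write_ct_long()`.
#' @param panel [gene_panel()] of the cohort.
#' @param passages Named character vector mapping chip id to passage label.
#' @param cycle_limit Cycle limit shared by all chips.
#' @rdname write_ct_long
#' @export
read_ct_long <- function(path, panel, passages, cycle_limit = 40L) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(colnames(df), .long_columns)) {
    stop("malformed header in ", path, " at line 1: expected ",
         paste(.long_columns, collapse = ","), call. = FALSE)
  }
  runs <- lapply(split(df, factor(df$chip_id, unique(df$chip_id))),
                 function(chunk) {
    cid <- chunk$chip_id[[1L]]
    if (!cid %in% names(passages)) {
      stop("no passage label supplied for chip '", cid, "'", call. = FALSE)
    }
    .chip_run_from_long(chunk, gene_panel(panel), passages[[cid]],
                        cycle_limit, path)
  })
  merge_runs(unname(runs))
}

#' @export
print.CtMatrix <- function(x, ...) {
  n_na <- sum(is.na(x$ct))
  cat(sprintf(
    "CtMatrix: %d cells x %d genes (cycle limit %d)\n", nrow(x$ct),
    length(x$genes), x$cycle_limit))
  cat(sprintf("  passages: %s\n",
              paste(sprintf("%s (%d)", names(table(x$cells$passage)),
                            table(x$cells$passage)), collapse = ", ")))
  cat(sprintf("  non-amplified reactions: %d (%.1f%%)\n", n_na,
              100 * n_na / length(x$ct)))
  invisible(x)
}
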