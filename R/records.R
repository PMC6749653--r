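#' Construct a validated pKa record table
#'
#' A record is one raw measurement: a SMILES, a pKa value and its class
#' (acidic or basic), optionally the measurement method and the number of
#' experimental values already averaged upstream.
#'
#' @param smiles Character vector of SMILES strings.
#' @param pka Numeric vector of pKa values (finite).
#' @param class Character vector, each `"acidic"` or `"basic"`.
#' @param method Optional character vector of measurement methods.
#' @param n_averaged Optional positive integer vector; number of
#'   experimental values averaged into each reported pKa.
#' @return A data.frame of class `pka_records`.
#' @export
pka_records <- function(smiles, pka, class, method = NULL, n_averaged = NULL) {
  stopifnot(is.character(smiles), length(smiles) == length(pka),
            length(class) == length(pka))
  pka <- as.numeric(pka)
  if (any(!is.finite(pka))) stop("all pKa values must be finite")
  class <- as.character(class)
  if (!all(class %in% c("acidic", "basic"))) {
    stop("`class` must be 'acidic' or 'basic'")
  }
  n <- length(smiles)
  method <- if (is.null(method)) rep(NA_character_, n) else as.character(method)
  n_averaged <- if (is.null(n_averaged)) rep(NA_integer_, n) else {
    na <- as.integer(n_averaged)
    if (any(!is.na(na) & na < 1L)) stop("`n_averaged` must be positive")
    na
  }
  out <- data.frame(smiles = smiles, pka = pka, class = class,
                    method = method, n_averaged = n_averaged,
                    stringsAsFactors = FALSE)
  class(out) <- c("pka_records", "data.frame")
  out
}

#' Read pKa records from a delimited file or SDF
#'
#' Delimited input (`.csv`, `.tsv`, `.txt`) must carry columns `smiles`,
#' `pka` and `class` (case-insensitive; `tsv`/`txt` are tab-separated).
#' SDF input is converted molecule-by-molecule through OpenBabel and must
#' carry `pka` and `class` data fields.
#'
#' @param path Path to the input file.
#' @return A `pka_records` data.frame.
#' @export
read_pka_records <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "sdf") {
    return(read_pka_records_sdf(path))
  }
  sep <- if (ext %in% c("tsv", "txt")) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (nrow(df) == 0L) stop("input file has no records: ", path)
  names(df) <- tolower(names(df))
  need <- c("smiles", "pka", "class")
  if (!all(need %in% names(df))) {
    stop("input must have columns smiles, pka, class (found: ",
         paste(names(df), collapse = ", "), ")")
  }
  pka_records(df$smiles, df$pka, df$class,
              method = if ("method" %in% names(df)) df$method else NULL,
              n_averaged = if ("n_averaged" %in% names(df)) df$n_averaged else NULL)
}

# minimal SDF reader: blocks separated by $$$$, SMILES regenerated via
# OpenBabel, pKa and class taken from the > <pka> / > <class> data fields
read_pka_records_sdf <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) == 0L) stop("input file has no records: ", path)
  ends <- grep("^\\$\\$\\$\\$", txt)
  if (length(ends) == 0L) stop("no SDF records found in ", path)
  starts <- c(1L, head(ends, -1L) + 1L)
  get_field <- function(block, name) {
    hit <- grep(paste0("^>\\s*<", name, ">"), block, ignore.case = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    trimws(block[hit[1] + 1L])
  }
  smiles <- character(0); pka <- numeric(0); cls <- character(0)
  for (b in seq_along(ends)) {
    block <- txt[starts[b]:ends[b]]
    mol <- paste(block[seq_len(length(block) - 1L)], collapse = "\n")
    smi <- tryCatch({
      out <- ChemmineOB::convertFormat("SDF", "CAN", paste0(mol, "\n"))
      strsplit(trimws(out), "[ \t\n]+")[[1]][1]
    }, error = function(e) NA_character_)
    p <- suppressWarnings(as.numeric(get_field(block, "pka")))
    k <- tolower(get_field(block, "class"))
    if (!is.na(smi) && !is.na(p) && k %in% c("acidic", "basic")) {
      smiles <- c(smiles, smi); pka <- c(pka, p); cls <- c(cls, k)
    }
  }
  if (length(smiles) == 0L) stop("no usable SDF records (need pka + class fields)")
  pka_records(smiles, pka, cls)
}

#' Write pKa records to CSV
#' @param records A `pka_records` data.frame.
#' @param path Output path.
#' @export
write_pka_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, na = "")
  invisible(path)
}
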