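#' @importFrom ChemmineOB convertFormat forEachMol prop_OB smartsSearch_OB
#'   fingerprint_OB
NULL

# --- low-level OpenBabel wrappers -------------------------------------------

# single-molecule format conversion; returns NA_character_ on failure
ob_convert <- function(smiles, to, options = NULL) {
  if (is.na(smiles) || !nzchar(trimws(smiles))) return(NA_character_)
  out <- tryCatch({
    if (is.null(options)) {
      ChemmineOB::convertFormat("SMI", to, smiles)
    } else {
      ChemmineOB::convertFormat("SMI", to, smiles, options = options)
    }
  }, error = function(e) "")
  out <- trimws(out)
  if (!nzchar(out)) return(NA_character_)
  # output lines are "value<TAB>title"; take the first token of the first line
  first <- strsplit(out, "\n", fixed = TRUE)[[1]][1]
  tok <- strsplit(trimws(first), "[ \t]+")[[1]][1]
  if (is.na(tok) || !nzchar(tok)) NA_character_ else tok
}

ob_canonical <- function(smiles) ob_convert(smiles, "CAN")

ob_inchi <- function(smiles) ob_convert(smiles, "INCHI")

ob_inchikey <- function(smiles) ob_convert(smiles, "INCHIKEY")

ob_neutralize <- function(smiles) {
  ob_convert(smiles, "CAN",
             options = data.frame(names = "neutralize", args = ""))
}

# molecular formula from the standard InChI formula layer
inchi_formula <- function(inchi) {
  if (is.na(inchi)) return(NA_character_)
  parts <- strsplit(inchi, "/", fixed = TRUE)[[1]]
  if (length(parts) < 2L) return("")
  parts[2]
}

# net formal charge from the InChI charge (/q) and protonation (/p)
# layers; zwitterions normalize to net zero so they are left untouched
inchi_net_charge <- function(inchi) {
  if (is.na(inchi)) return(0L)
  q <- regmatches(inchi, regexec("/q([+-]?[0-9]+)", inchi))[[1]]
  p <- regmatches(inchi, regexec("/p([+-]?[0-9]+)", inchi))[[1]]
  (if (length(q) == 2L) as.integer(q[2]) else 0L) +
    (if (length(p) == 2L) as.integer(p[2]) else 0L)
}

# carbon presence decided on the InChI formula layer, which is exact
# (avoids confusing the element C with Cl/Ca/Cd/... in raw SMILES)
formula_has_carbon <- function(formula) {
  if (is.na(formula)) return(NA)
  grepl("C(?![a-z])", formula, perl = TRUE)
}

# count of SMARTS matches on a single molecule (unique matches)
ob_smarts_count <- function(smiles, smarts) {
  res <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, function(m) {
      ChemmineOB::smartsSearch_OB(list(m), smarts, uniqueMatches = TRUE)
    }),
    error = function(e) NA_integer_)
  if (length(res) == 0L) return(NA_integer_)
  as.integer(res[[1]])
}

# --- strip list --------------------------------------------------------------

# organic fragments treated as solvents / organic counterions: stripped only
# when at least one other organic fragment remains
.strip_list_smiles <- c(
  ethanol         = "CCO",
  methanol        = "CO",
  isopropanol     = "CC(C)O",
  acetone         = "CC(C)=O",
  acetonitrile    = "CC#N",
  dmso            = "CS(C)=O",
  diethyl_ether   = "CCOCC",
  thf             = "C1CCOC1",
  dichloromethane = "ClCCl",
  chloroform      = "ClC(Cl)Cl",
  tosylate        = "Cc1ccc(S(=O)(=O)[O-])cc1",
  tosylic_acid    = "Cc1ccc(S(=O)(=O)O)cc1",
  mesylate        = "CS(=O)(=O)[O-]",
  mesylic_acid    = "CS(=O)(=O)O",
  trifluoroacetate = "[O-]C(=O)C(F)(F)F",
  trifluoroacetic  = "OC(=O)C(F)(F)F",
  oxalic_acid     = "OC(=O)C(=O)O",
  maleic_acid     = "OC(=O)/C=C\\C(=O)O"
)

.pkg_cache <- new.env(parent = emptyenv())

strip_list_keys <- function() {
  if (is.null(.pkg_cache$strip_keys)) {
    keys <- vapply(.strip_list_smiles, ob_inchikey, character(1))
    .pkg_cache$strip_keys <- keys[!is.na(keys)]
  }
  .pkg_cache$strip_keys
}

# --- tautomer normalization --------------------------------------------------

# nitro mesomers: rewrite the uncharged N(=O)=O form to the charge-separated
# canonical representation
normalize_nitro <- function(smiles) {
  s <- gsub("N(=O)=O", "[N+](=O)[O-]", smiles, fixed = TRUE)
  s <- gsub("O=N(=O)", "O=[N+]([O-])", s, fixed = TRUE)
  s
}

# terminal enols (CH2=C(-OH)R and CH2=CH-OH) are mapped to their carbonyl
# tautomer; internal enols are left alone (rule scope documented in the
# methods vignette)
normalize_enol <- function(smiles) {
  n_enol <- ob_smarts_count(smiles, "[CH2X3]=[CX3][OX2H1]")
  if (is.na(n_enol) || n_enol == 0L) return(smiles)
  cand <- smiles
  if (grepl("C(=C)O", cand, fixed = TRUE)) {
    cand <- sub("C(=C)O", "C(C)=O", cand, fixed = TRUE)
  } else if (startsWith(cand, "OC=C")) {
    cand <- sub("^OC=C", "O=CC", cand)
  } else if (grepl("(OC=C", cand, fixed = TRUE)) {
    cand <- sub("(OC=C", "(O=CC", cand, fixed = TRUE)
  } else {
    return(smiles)
  }
  recan <- ob_canonical(cand)
  if (is.na(recan)) return(smiles)
  left <- ob_smarts_count(recan, "[CH2X3]=[CX3][OX2H1]")
  if (!is.na(left) && left < n_enol) recan else smiles
}

normalize_tautomers <- function(smiles) {
  s <- normalize_nitro(smiles)
  s <- ob_canonical(s)
  if (is.na(s)) return(NA_character_)
  # repeat until no terminal enol rewrite applies (at most a few rounds)
  for (i in 1:4) {
    s2 <- normalize_enol(s)
    if (identical(s2, s)) break
    s <- s2
  }
  s
}

# --- standardization ---------------------------------------------------------

#' Standardize a raw SMILES to a QSAR-ready parent structure
#'
#' Applies the curation rules used to prepare pKa modeling sets: the input
#' is split into components; carbon-free components (counterions, water,
#' inorganic salts) are stripped; common solvent and organic-counterion
#' fragments are stripped when another organic fragment is present;
#' inputs with two or more distinct organic fragments are rejected as
#' mixtures and carbon-free inputs as inorganic; the surviving parent is
#' charge-neutralized unless it is a zwitterion (zwitterions are kept
#' unmodified); nitro mesomers and terminal keto-enol tautomers are mapped
#' to one canonical form. The structure key is the standard InChIKey of
#' the final parent, so mesomers and protomers deduplicate together.
#'
#' @param smiles A single SMILES string.
#' @return A one-row data.frame with columns `smiles_raw`,
#'   `canonical_smiles`, `structure_key`, `rejected`, `rejection_reason`.
#'   For rejected inputs `canonical_smiles` and `structure_key` are `NA`
#'   and `rejection_reason` is one of `"inorganic"`, `"mixture"`,
#'   `"empty_after_stripping"`.
#' @examples
#' \donttest{
#' standardize_structure("CC(=O)[O-].[Na+]")  # sodium acetate -> acetic acid
#' standardize_structure("c1ccccc1")          # benzene, unchanged
#' }
#' @seealso [standardize_structures()] for the vectorized form.
#' @export
standardize_structure <- function(smiles) {
  res <- standardize_structures(smiles, on_parse_error = "error")
  res
}

#' Standardize a vector of SMILES
#'
#' Vectorized version of [standardize_structure()].
#'
#' @param smiles Character vector of SMILES strings.
#' @param on_parse_error `"error"` (default) stops on the first unparsable
#'   SMILES; `"reject"` marks the row rejected with reason `"parse_error"`.
#' @return A data.frame with one row per input, columns as in
#'   [standardize_structure()].
#' @export
standardize_structures <- function(smiles,
                                   on_parse_error = c("error", "reject")) {
  on_parse_error <- match.arg(on_parse_error)
  stopifnot(is.character(smiles))
  n <- length(smiles)
  out <- data.frame(
    smiles_raw = smiles,
    canonical_smiles = NA_character_,
    structure_key = NA_character_,
    rejected = FALSE,
    rejection_reason = NA_character_,
    stringsAsFactors = FALSE
  )
  strip_keys <- strip_list_keys()
  for (i in seq_len(n)) {
    s <- trimws(smiles[i])
    if (!nzchar(s) || is.na(s)) {
      if (on_parse_error == "error") stop("empty SMILES at position ", i)
      out$rejected[i] <- TRUE; out$rejection_reason[i] <- "parse_error"
      next
    }
    comps <- strsplit(s, ".", fixed = TRUE)[[1]]
    can <- vapply(comps, ob_canonical, character(1), USE.NAMES = FALSE)
    if (anyNA(can)) {
      if (on_parse_error == "error") {
        stop("unparsable SMILES at position ", i, ": ", s)
      }
      out$rejected[i] <- TRUE; out$rejection_reason[i] <- "parse_error"
      next
    }
    inchi <- vapply(can, ob_inchi, character(1), USE.NAMES = FALSE)
    keys <- vapply(can, ob_inchikey, character(1), USE.NAMES = FALSE)
    has_c <- vapply(inchi, function(x) {
      isTRUE(formula_has_carbon(inchi_formula(x)))
    }, logical(1))

    org_idx <- which(has_c)
    if (length(org_idx) == 0L) {
      out$rejected[i] <- TRUE; out$rejection_reason[i] <- "inorganic"
      next
    }
    # collapse identical organic components (e.g. "CCO.CCO")
    org_keys <- keys[org_idx]
    uniq <- org_idx[!duplicated(org_keys)]
    if (length(uniq) >= 2L) {
      keep <- uniq[!(keys[uniq] %in% strip_keys)]
      if (length(keep) == 0L) {
        out$rejected[i] <- TRUE
        out$rejection_reason[i] <- "empty_after_stripping"
        next
      }
      if (length(keep) >= 2L) {
        out$rejected[i] <- TRUE; out$rejection_reason[i] <- "mixture"
        next
      }
      uniq <- keep
    }
    parent <- can[uniq]

    # neutralize parents with non-zero net charge (salt residues);
    # zwitterions carry net zero and are kept as-is
    if (inchi_net_charge(inchi[uniq]) != 0L) {
      neut <- ob_neutralize(parent)
      if (!is.na(neut)) parent <- neut
    }

    parent <- normalize_tautomers(parent)
    if (is.na(parent)) {
      if (on_parse_error == "error") {
        stop("standardization failed for SMILES at position ", i, ": ", s)
      }
      out$rejected[i] <- TRUE; out$rejection_reason[i] <- "parse_error"
      next
    }
    out$canonical_smiles[i] <- parent
    out$structure_key[i] <- ob_inchikey(parent)
  }
  out
}
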