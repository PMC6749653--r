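# SMARTS fragment-count table: names become feature columns prefixed "frag_"
.fragment_smarts <- c(
  hydroxyl          = "[OX2H]",
  alcohol_oh        = "[OX2H][CX4]",
  phenol_oh         = "[OX2H][c]",
  carboxylic_acid   = "[CX3](=O)[OX2H1]",
  carboxylate       = "[CX3](=O)[O-]",
  ester             = "[CX3](=O)[OX2H0][#6]",
  ether             = "[OX2H0]([#6])[#6]",
  ketone            = "[CX3](=O)([#6])[#6]",
  aldehyde          = "[CX3H1](=O)",
  amide             = "[NX3][CX3](=O)",
  primary_amine     = "[NX3;H2;!$(NC=O)]",
  secondary_amine   = "[NX3;H1;!$(NC=O)]",
  tertiary_amine    = "[NX3;H0;!$(NC=O);!$(N=*);!n]",
  aromatic_n        = "[n]",
  pyridine_n        = "[nX2H0]",
  pyrrole_nh        = "[nH]",
  nitro             = "[$([NX3](=O)=O),$([NX3+](=O)[O-])]",
  nitrile           = "[NX1]#[CX2]",
  guanidine         = "[NX3][CX3](=[NX2])[NX3]",
  sulfonic_acid     = "[SX4](=O)(=O)[OX2H1]",
  sulfonamide       = "[SX4](=O)(=O)[NX3]",
  thiol             = "[SX2H]",
  thioether         = "[SX2H0]([#6])[#6]",
  phosphoryl        = "[PX4](=O)",
  halogen_f         = "[F]",
  halogen_cl        = "[Cl]",
  halogen_br        = "[Br]",
  halogen_i         = "[I]",
  benzene_ring      = "c1ccccc1",
  imidazole_ring    = "c1cnc[nH]1"
)

# family aliases: names used by other descriptor engines mapped to the
# fingerprints this stack actually computes
.family_aliases <- c(cdk_like = "fp2", pubchem = "fp4")

.known_families <- c("continuous_1d2d", "maccs", "fp2", "fp3", "fp4",
                     "substructure_counts", "atom_pairs")

resolve_families <- function(families) {
  families <- as.character(families)
  families[families %in% names(.family_aliases)] <-
    .family_aliases[families[families %in% names(.family_aliases)]]
  bad <- setdiff(families, .known_families)
  if (length(bad)) {
    stop("unknown feature families: ", paste(bad, collapse = ", "),
         " (known: ", paste(.known_families, collapse = ", "), ")")
  }
  unique(families)
}

# parse the V2000 connection table of a single-molecule SDF string into an
# atom element vector and a bond index matrix
parse_ctab <- function(sdf_text) {
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) return(NULL)
  counts <- lines[4]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || n_atoms < 1L) return(NULL)
  atom_lines <- lines[5:(4 + n_atoms)]
  elem <- trimws(substr(atom_lines, 32, 34))
  bonds <- NULL
  if (!is.na(n_bonds) && n_bonds > 0L) {
    bond_lines <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    bonds <- cbind(as.integer(substr(bond_lines, 1, 3)),
                   as.integer(substr(bond_lines, 4, 6)))
  }
  list(elem = elem, bonds = bonds)
}

# topological (bond-count) distance matrix by BFS on the heavy-atom graph
topo_distances <- function(n_atoms, bonds, max_d = 6L) {
  adj <- vector("list", n_atoms)
  if (!is.null(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  d <- matrix(NA_integer_, n_atoms, n_atoms)
  for (s in seq_len(n_atoms)) {
    dist <- rep(NA_integer_, n_atoms); dist[s] <- 0L
    frontier <- s
    depth <- 0L
    while (length(frontier) && depth < max_d) {
      depth <- depth + 1L
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      dist[nxt] <- depth
      frontier <- nxt
    }
    d[s, ] <- dist
  }
  d
}

# atom-pair counts for one molecule: element pairs at topological distance
# 1..max_d, hydrogen excluded
atom_pair_counts <- function(smiles, max_d = 6L) {
  sdf <- tryCatch(ChemmineOB::convertFormat("SMI", "SDF", smiles),
                  error = function(e) NULL)
  if (is.null(sdf) || !nzchar(sdf)) return(NULL)
  ct <- parse_ctab(sdf)
  if (is.null(ct)) return(NULL)
  heavy <- which(ct$elem != "H")
  if (length(heavy) < 2L) return(integer(0))
  # reindex bonds onto heavy atoms
  map <- match(seq_along(ct$elem), heavy)
  bonds <- ct$bonds
  if (!is.null(bonds)) {
    keep <- !is.na(map[bonds[, 1]]) & !is.na(map[bonds[, 2]])
    bonds <- cbind(map[bonds[keep, 1]], map[bonds[keep, 2]])
  }
  elem <- ct$elem[heavy]
  d <- topo_distances(length(heavy), bonds, max_d = max_d)
  counts <- integer(0)
  for (i in seq_len(length(heavy) - 1L)) {
    for (j in (i + 1L):length(heavy)) {
      dij <- d[i, j]
      if (is.na(dij) || dij == 0L) next
      pair <- sort(c(elem[i], elem[j]))
      nm <- paste0("ap_", pair[1], "_", pair[2], "_", dij)
      counts[nm] <- (if (nm %in% names(counts)) counts[[nm]] else 0L) + 1L
    }
  }
  counts
}

# continuous 1D/2D descriptors for one parsed molecule
continuous_descriptors <- function(m, smiles) {
  pr <- ChemmineOB::prop_OB(list(m))
  formula <- inchi_formula(pr$InChI)
  count_elem <- function(el) {
    hits <- gregexpr(paste0(el, "(?![a-z])([0-9]*)"), formula, perl = TRUE)[[1]]
    if (hits[1] == -1) return(0L)
    lens <- attr(hits, "match.length")
    tot <- 0L
    for (h in seq_along(hits)) {
      tok <- substr(formula, hits[h], hits[h] + lens[h] - 1L)
      num <- sub(paste0("^", el), "", tok)
      tot <- tot + if (nzchar(num)) as.integer(num) else 1L
    }
    tot
  }
  sdf <- tryCatch(ChemmineOB::convertFormat("SMI", "SDF", smiles),
                  error = function(e) NULL)
  ct <- if (!is.null(sdf)) parse_ctab(sdf) else NULL
  n_heavy <- if (!is.null(ct)) sum(ct$elem != "H") else NA_integer_
  n_bonds_heavy <- if (!is.null(ct) && !is.null(ct$bonds)) {
    heavy <- ct$elem != "H"
    sum(heavy[ct$bonds[, 1]] & heavy[ct$bonds[, 2]])
  } else 0L
  n_rings <- if (!is.na(n_heavy) && n_heavy > 0L) {
    max(0L, n_bonds_heavy - n_heavy + 1L)
  } else NA_integer_
  # aromatic atoms read off the canonical SMILES organic-subset letters
  can <- pr$cansmi
  no_br <- gsub("\\[[^][]*\\]", "", can)
  n_arom <- sum(vapply(c("b", "c", "n", "o", "p", "s"), function(ch) {
    lengths(regmatches(no_br, gregexpr(ch, no_br, fixed = TRUE)))
  }, integer(1))) - lengths(regmatches(no_br, gregexpr("se", no_br)))
  nC <- count_elem("C"); nN <- count_elem("N"); nO <- count_elem("O")
  nS <- count_elem("S"); nP <- count_elem("P")
  nHal <- count_elem("F") + count_elem("Cl") + count_elem("Br") +
    count_elem("I")
  c(MW = pr$MW, logP = pr$logP, TPSA = pr$TPSA, MR = pr$MR,
    HBD = pr$HBD, HBA = pr$HBA1, HBA2 = pr$HBA2, nF = pr$nF,
    nC = nC, nN = nN, nO = nO, nS = nS, nP = nP, nHal = nHal,
    nHeavy = as.numeric(n_heavy), nRings = as.numeric(n_rings),
    nAromAtoms = as.numeric(n_arom),
    fracArom = if (!is.na(n_heavy) && n_heavy > 0) n_arom / n_heavy else 0,
    heteroRatio = if (nC > 0) (nN + nO + nS) / nC else nN + nO + nS)
}

#' Compute descriptor, fingerprint and fragment-count features
#'
#' One row per structure; columns carry family prefixes
#' (`desc_`, `maccs_`, `fp2_`, `fp3_`, `fp4_`, `frag_`, `ap_`).
#' Continuous descriptor columns containing any missing value are dropped.
#' Structures that fail featurization are excluded and listed in the
#' `failed` attribute.
#'
#' @param structures Result of [standardize_structures()] (non-rejected
#'   rows are used), or a character vector of SMILES.
#' @param families Character vector of feature families:
#'   `"continuous_1d2d"`, `"maccs"` (166 keys), `"fp2"` (1024-bit path
#'   fingerprint), `"fp3"`, `"fp4"` (SMARTS-key fingerprints),
#'   `"substructure_counts"`, `"atom_pairs"`. The aliases `"cdk_like"`
#'   (-> fp2) and `"pubchem"` (-> fp4) are accepted.
#' @return A `pka_features` object: a numeric matrix in `$values` with
#'   structure keys as row names, plus `kind`, `reduction` (starts at
#'   `"D0"`), `families` and `failed`.
#' @export
compute_features <- function(structures,
                             families = c("continuous_1d2d", "maccs")) {
  families <- resolve_families(families)
  if (is.character(structures)) {
    smiles <- structures
    keys <- if (!is.null(names(structures))) names(structures) else structures
  } else {
    stopifnot(is.data.frame(structures))
    ok <- !structures$rejected
    smiles <- structures$canonical_smiles[ok]
    keys <- structures$structure_key[ok]
  }
  dup <- duplicated(keys)
  smiles <- smiles[!dup]; keys <- keys[!dup]
  n <- length(smiles)
  if (n == 0L) stop("no structures to featurize")

  rows <- vector("list", n)
  failed <- character(0)
  for (i in seq_len(n)) {
    feats <- tryCatch(
      ChemmineOB::forEachMol("SMILES", smiles[i], function(m) {
        out <- list()
        if ("continuous_1d2d" %in% families) {
          v <- continuous_descriptors(m, smiles[i])
          out$cont <- setNames(as.numeric(v), paste0("desc_", names(v)))
        }
        for (fp in intersect(c("maccs", "fp2", "fp3", "fp4"), families)) {
          bits <- ChemmineOB::fingerprint_OB(list(m), toupper(fp))
          bits <- as.numeric(bits)
          if (fp == "maccs") bits <- bits[seq_len(166L)]
          out[[fp]] <- setNames(bits, sprintf("%s_%04d", fp, seq_along(bits)))
        }
        if ("substructure_counts" %in% families) {
          cnt <- vapply(.fragment_smarts, function(pat) {
            as.numeric(ChemmineOB::smartsSearch_OB(list(m), pat,
                                                   uniqueMatches = TRUE))
          }, numeric(1))
          out$frag <- setNames(cnt, paste0("frag_", names(.fragment_smarts)))
        }
        out
      })[[1]],
      error = function(e) NULL)
    if (is.null(feats)) { failed <- c(failed, keys[i]); next }
    vec <- unlist(feats, use.names = TRUE)
    if (is.null(vec)) vec <- numeric(0)
    names(vec) <- sub("^(cont|maccs|fp2|fp3|fp4|frag)\\.", "", names(vec))
    if ("atom_pairs" %in% families) {
      ap <- atom_pair_counts(smiles[i])
      if (is.null(ap)) { failed <- c(failed, keys[i]); next }
      if (length(ap)) vec <- c(vec, ap)
    }
    rows[[i]] <- vec
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("featurization failed for every structure")
  rows <- rows[keep]
  all_names <- unique(unlist(lapply(rows, names)))
  mat <- matrix(0, nrow = length(rows), ncol = length(all_names),
                dimnames = list(keys[keep], all_names))
  for (r in seq_along(rows)) {
    mat[r, names(rows[[r]])] <- rows[[r]]
  }
  # drop descriptor columns with missing values (other families default 0)
  has_na <- colSums(is.na(mat)) > 0L
  mat <- mat[, !has_na, drop = FALSE]

  kinds <- c(continuous_1d2d = "continuous", maccs = "binary",
             fp2 = "binary", fp3 = "binary", fp4 = "binary",
             substructure_counts = "count", atom_pairs = "count")
  fam_kinds <- unique(unname(kinds[families]))
  kind <- if (length(fam_kinds) == 1L) fam_kinds else "mixed"

  new_pka_features(mat, kind = kind, reduction = "D0",
                   families = families, failed = failed)
}

new_pka_features <- function(values, kind, reduction, families,
                             failed = character(0)) {
  stopifnot(is.matrix(values))
  if (anyDuplicated(colnames(values))) stop("duplicate feature names")
  structure(list(values = values, kind = kind, reduction = reduction,
                 families = families, failed = failed),
            class = "pka_features")
}

#' @export
print.pka_features <- function(x, ...) {
  cat(sprintf("pka_features: %d structures x %d features [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$kind, x$reduction))
  cat("families:", paste(x$families, collapse = ", "), "\n")
  if (length(x$failed)) cat("failed structures:", length(x$failed), "\n")
  invisible(x)
}

#' Apply the D1/D2/D3 feature-reduction ladder
#'
#' `D1` removes constant columns (including all-zero and all-one
#' fingerprint bits). `D2` additionally removes one column of every pair
#' with absolute Pearson correlation at or above `corr_threshold`
#' (scanning columns left to right and keeping the first of each
#' correlated pair). `D3` additionally removes columns with variance
#' below `var_threshold`. Each level starts from the previous one, so
#' column sets are nested.
#'
#' @param fm A `pka_features` object.
#' @param level `"D1"`, `"D2"` or `"D3"`.
#' @param corr_threshold Absolute correlation cutoff for D2 (default 0.95).
#' @param var_threshold Variance floor for D3 (default 0.01).
#' @return A reduced `pka_features` object (row order preserved).
#' @export
reduce_features <- function(fm, level = c("D1", "D2", "D3"),
                            corr_threshold = 0.95, var_threshold = 0.01) {
  stopifnot(inherits(fm, "pka_features"))
  level <- match.arg(level)
  m <- fm$values
  if (ncol(m) < 1L) stop("feature matrix has no columns")

  # D1: constant columns out
  keep <- apply(m, 2, function(x) length(unique(x)) > 1L)
  m <- m[, keep, drop = FALSE]
  if (ncol(m) == 0L) stop("all columns removed at D1")

  if (level %in% c("D2", "D3")) {
    cm <- suppressWarnings(abs(stats::cor(m)))
    cm[is.na(cm)] <- 0
    drop <- rep(FALSE, ncol(m))
    for (j in seq_len(ncol(m))[-1]) {
      earlier <- which(!drop[seq_len(j - 1L)])
      if (length(earlier) && any(cm[earlier, j] >= corr_threshold)) {
        drop[j] <- TRUE
      }
    }
    m <- m[, !drop, drop = FALSE]
    if (ncol(m) == 0L) stop("all columns removed at D2")
  }
  if (level == "D3") {
    v <- apply(m, 2, stats::var)
    m <- m[, v >= var_threshold, drop = FALSE]
    if (ncol(m) == 0L) stop("all columns removed at D3")
  }
  new_pka_features(m, kind = fm$kind, reduction = level,
                   families = fm$families, failed = fm$failed)
}

#' Fit a min-max scaling specification on training features
#'
#' Columns are mapped linearly so that the training minimum and maximum
#' land on -1 and +1. Zero-range columns map to 0. Rows outside the
#' training range (e.g. test structures) may fall outside \[-1, 1\].
#'
#' @param fm A `pka_features` object or numeric matrix (training rows only).
#' @return A `scaling_spec` object with per-column `min` and `max`.
#' @export
fit_scaling <- function(fm) {
  m <- if (inherits(fm, "pka_features")) fm$values else fm
  stopifnot(is.matrix(m))
  structure(list(min = apply(m, 2, min), max = apply(m, 2, max),
                 columns = colnames(m)),
            class = "scaling_spec")
}

#' Apply (or invert) a fitted scaling specification
#'
#' @param fm A `pka_features` object or numeric matrix.
#' @param spec A `scaling_spec` from [fit_scaling()].
#' @param invert If `TRUE`, map scaled values back to the original range.
#' @return Same type as `fm`, with transformed values.
#' @export
apply_scaling <- function(fm, spec, invert = FALSE) {
  stopifnot(inherits(spec, "scaling_spec"))
  m <- if (inherits(fm, "pka_features")) fm$values else fm
  if (!identical(colnames(m), spec$columns)) {
    if (!all(spec$columns %in% colnames(m))) {
      stop("feature matrix lacks columns required by the scaling spec")
    }
    m <- m[, spec$columns, drop = FALSE]
  }
  rng <- spec$max - spec$min
  zero <- rng == 0
  out <- m
  for (j in seq_len(ncol(m))) {
    if (zero[j]) {
      out[, j] <- if (invert) spec$min[j] else 0
    } else if (invert) {
      out[, j] <- (m[, j] + 1) / 2 * rng[j] + spec$min[j]
    } else {
      out[, j] <- 2 * (m[, j] - spec$min[j]) / rng[j] - 1
    }
  }
  if (inherits(fm, "pka_features")) {
    fm$values <- out
    fm
  } else {
    out
  }
}
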