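# Template library for the synthetic record generator. Each template has
# a SMILES builder with up to two aromatic substitution sites (or an
# aliphatic chain), a class, and base pKa values for a deliberately
# simple additive group-contribution oracle: decorations shift the base
# value (electron-withdrawing groups lower it), a second (meta) site
# contributes at 60% strength, and each extra chain carbon adds +0.04.
# The oracle exists to make signal learnable by the regressors, not to be
# chemically accurate.

.fixture_decorations <- list(
  H       = list(frag = "",                 effect = 0),
  methyl  = list(frag = "C",                effect = 0.2),
  ethyl   = list(frag = "CC",               effect = 0.25),
  propyl  = list(frag = "CCC",              effect = 0.28),
  butyl   = list(frag = "CCCC",             effect = 0.30),
  methoxy = list(frag = "OC",               effect = 0.15),
  fluoro  = list(frag = "F",                effect = -0.5),
  chloro  = list(frag = "Cl",               effect = -0.7),
  bromo   = list(frag = "Br",               effect = -0.6),
  cyano   = list(frag = "C#N",              effect = -1.3),
  nitro   = list(frag = "[N+](=O)[O-]",     effect = -1.9)
)

# two-site aromatic builder: para (R1) and meta (R2) positions
aryl_smiles <- function(core_prefix, d1, d2) {
  f1 <- .fixture_decorations[[d1]]$frag
  f2 <- .fixture_decorations[[d2]]$frag
  mid <- if (nzchar(f1) && nzchar(f2)) {
    paste0("c1ccc(", f1, ")c(", f2, ")c1")
  } else if (nzchar(f1)) {
    paste0("c1ccc(", f1, ")cc1")
  } else if (nzchar(f2)) {
    paste0("c1cccc(", f2, ")c1")
  } else {
    "c1ccccc1"
  }
  paste0(core_prefix, mid)
}

.fixture_templates <- list(
  benzoic_acid = list(kind = "aryl2", prefix = "OC(=O)",
                      class = "acidic", acidic = 4.2),
  phenol = list(kind = "aryl2", prefix = "O",
                class = "acidic", acidic = 10.0),
  benzenesulfonamide = list(kind = "aryl2", prefix = "NS(=O)(=O)",
                            class = "acidic", acidic = 10.1),
  aliphatic_acid = list(kind = "chain", class = "acidic", acidic = 4.76,
                        build = function(chain) {
                          paste0("OC(=O)", strrep("C", chain + 1L))
                        }),
  alkyl_amine = list(kind = "chain", class = "basic", basic = 10.6,
                     build = function(chain) {
                       paste0("N", strrep("C", chain + 1L))
                     }),
  aniline = list(kind = "aryl2", prefix = "N",
                 class = "basic", basic = 4.6),
  pyridine = list(kind = "aryl1", class = "basic", basic = 5.2,
                  build = function(frag) {
                    if (nzchar(frag)) paste0("c1cc(", frag, ")ccn1")
                    else "c1ccncc1"
                  }),
  imidazole = list(kind = "aryl1", class = "basic", basic = 7.0,
                   build = function(frag) {
                     if (nzchar(frag)) paste0("c1ncc(", frag, ")[nH]1")
                     else "c1ncc[nH]1"
                   }),
  amino_acid = list(kind = "chain", class = "amphoteric",
                    acidic = 2.3, basic = 9.6,
                    build = function(chain) {
                      if (chain == 0L) "NCC(=O)O"
                      else paste0("NC(", strrep("C", chain), ")C(=O)O")
                    }),
  aminophenol = list(kind = "aryl2_custom", class = "amphoteric",
                     acidic = 10.2, basic = 4.4,
                     build = function(f1, f2) {
                       s1 <- if (nzchar(f1)) paste0("(", f1, ")") else ""
                       s2 <- if (nzchar(f2)) paste0("(", f2, ")") else ""
                       paste0("Nc1cc", s1, "c(O)c", s2, "c1")
                     }),
  anthranilic_acid = list(kind = "aryl2_custom", class = "amphoteric",
                          acidic = 4.9, basic = 2.1,
                          build = function(f1, f2) {
                            s1 <- if (nzchar(f1)) paste0("(", f1, ")") else ""
                            s2 <- if (nzchar(f2)) paste0("(", f2, ")") else ""
                            paste0("Nc1cc", s1, "cc", s2, "c1C(=O)O")
                          })
)

.fixture_inorganics <- data.frame(
  smiles = c("[Na+].[Cl-]", "OP(=O)(O)O", "OS(=O)(=O)O", "N", "O"),
  pka = c(7.0, 2.1, 1.9, 9.2, 13.9),
  class = c("acidic", "acidic", "acidic", "basic", "acidic"),
  stringsAsFactors = FALSE
)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Ground-truth pKa oracle for fixture templates
#'
#' Deterministic additive value used by the synthetic generator:
#' template base value + decoration effects (second site at 60% weight)
#' + 0.04 per extra chain carbon, clamped into the modeled range
#' (\[0, 14\] acidic, \[-2, 12\] basic).
#'
#' @param template Template name (see the fixture library).
#' @param class `"acidic"` or `"basic"`; must be available for the
#'   template.
#' @param decorations Character vector of up to two decoration names
#'   (default none).
#' @param chain Extra chain carbons (default 0).
#' @return The oracle pKa value.
#' @export
oracle_pka <- function(template, class = c("acidic", "basic"),
                       decorations = character(0), chain = 0L) {
  class <- match.arg(class)
  tpl <- .fixture_templates[[template]]
  if (is.null(tpl)) stop("unknown template: ", template)
  base <- tpl[[class]]
  if (is.null(base)) stop("template ", template, " has no ", class, " pKa")
  bad <- setdiff(decorations, names(.fixture_decorations))
  if (length(bad)) stop("unknown decorations: ", paste(bad, collapse = ", "))
  eff <- 0
  if (length(decorations) >= 1L) {
    eff <- eff + .fixture_decorations[[decorations[1]]]$effect
  }
  if (length(decorations) >= 2L) {
    eff <- eff + 0.6 * .fixture_decorations[[decorations[2]]]$effect
  }
  val <- base + eff + 0.04 * chain
  if (class == "acidic") clamp(val, 0.3, 13.7) else clamp(val, -1.7, 11.7)
}

# enumerate the deterministic pool of distinct fixture structures
fixture_pool <- function() {
  if (!is.null(.pkg_cache$fixture_pool)) return(.pkg_cache$fixture_pool)
  dn <- names(.fixture_decorations)
  rows <- list()
  add <- function(template, smiles, decorations, chain) {
    tpl <- .fixture_templates[[template]]
    acid <- if (!is.null(tpl$acidic)) {
      oracle_pka(template, "acidic", decorations, chain)
    } else NA_real_
    bas <- if (!is.null(tpl$basic)) {
      oracle_pka(template, "basic", decorations, chain)
    } else NA_real_
    rows[[length(rows) + 1L]] <<- data.frame(
      template = template, smiles = smiles,
      deco1 = if (length(decorations) >= 1L) decorations[1] else "H",
      deco2 = if (length(decorations) >= 2L) decorations[2] else "H",
      chain = chain, class_type = tpl$class,
      oracle_acidic = acid, oracle_basic = bas,
      stringsAsFactors = FALSE)
  }
  for (nm in names(.fixture_templates)) {
    tpl <- .fixture_templates[[nm]]
    if (tpl$kind == "aryl2") {
      for (d1 in dn) for (d2 in dn) {
        add(nm, aryl_smiles(tpl$prefix, d1, d2), c(d1, d2), 0L)
      }
    } else if (tpl$kind == "aryl2_custom") {
      for (d1 in dn) for (d2 in dn) {
        add(nm, tpl$build(.fixture_decorations[[d1]]$frag,
                          .fixture_decorations[[d2]]$frag), c(d1, d2), 0L)
      }
    } else if (tpl$kind == "aryl1") {
      for (d1 in dn) {
        add(nm, tpl$build(.fixture_decorations[[d1]]$frag), d1, 0L)
      }
    } else {
      for (ch in 0:9) add(nm, tpl$build(ch), character(0), ch)
    }
  }
  pool <- do.call(rbind, rows)
  # symmetric substitution patterns can collide on the same molecule;
  # deduplicate on the InChIKey so sampled structures are truly distinct
  pool$structure_key <- vapply(pool$smiles, ob_inchikey, character(1),
                               USE.NAMES = FALSE)
  pool <- pool[!is.na(pool$structure_key) &
                 !duplicated(pool$structure_key), , drop = FALSE]
  rownames(pool) <- NULL
  .pkg_cache$fixture_pool <- pool
  pool
}

#' Specification for the synthetic record generator
#'
#' Defaults emulate the statistical shape of a curated experimental pKa
#' collection: about a quarter of structures amphoteric, most structures
#' measured once, replicate standard deviations mostly below 1 pKa unit
#' with a mid (1-2) and a high (>2) tail, some records presented as salt
#' forms, and small fractions of mixture and inorganic records that the
#' curation stage must reject.
#'
#' @param n_structures Number of distinct valid parent structures.
#' @param pct_amphoteric Fraction of structures drawn from amphoteric
#'   templates (exact count, rounded).
#' @param replicate_profile Named numeric vector: group size ->
#'   frequency; must sum to 1.
#' @param sd_profile Named vector with entries `low`, `mid`, `high`
#'   summing to 1: mixture of replicate-SD bands (<1, 1-2, >2 pKa units).
#' @param pct_salts Fraction of records emitted as salt forms.
#' @param pct_mixtures,pct_inorganics Fractions (of `n_structures`) of
#'   extra mixture / inorganic records injected.
#' @param noise_sd Gaussian noise added to the oracle value (pKa units).
#' @param seed Integer seed; generation is fully deterministic per seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_structures = 300L, pct_amphoteric = 0.25,
                         replicate_profile = c("1" = 0.75, "2" = 0.13,
                                               "3" = 0.08, "4" = 0.04),
                         sd_profile = c(low = 0.72, mid = 0.16,
                                        high = 0.12),
                         pct_salts = 0.08, pct_mixtures = 0.03,
                         pct_inorganics = 0.03, noise_sd = 0.4,
                         seed = 1L) {
  stopifnot(n_structures >= 1L)
  for (p in c(pct_amphoteric, pct_salts, pct_mixtures, pct_inorganics)) {
    assert_scalar_number(p, "fraction", lo = 0, hi = 1)
  }
  if (pct_mixtures + pct_inorganics > 1) {
    stop("infeasible spec: pct_mixtures + pct_inorganics > 1")
  }
  if (abs(sum(replicate_profile) - 1) > 1e-8) {
    stop("replicate_profile frequencies must sum to 1")
  }
  if (abs(sum(sd_profile) - 1) > 1e-8 ||
      !all(c("low", "mid", "high") %in% names(sd_profile))) {
    stop("sd_profile must have low/mid/high entries that sum to 1")
  }
  structure(list(n_structures = as.integer(n_structures),
                 pct_amphoteric = pct_amphoteric,
                 replicate_profile = replicate_profile,
                 sd_profile = sd_profile, pct_salts = pct_salts,
                 pct_mixtures = pct_mixtures,
                 pct_inorganics = pct_inorganics, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# replicate values with an exactly realized sample SD around a center
replicate_values <- function(center, g, target_sd) {
  if (g == 1L) return(center)
  base <- seq_len(g) - (g + 1) / 2
  base <- base / stats::sd(base)
  center + base * target_sd
}

#' Generate a synthetic pKa record set
#'
#' Draws distinct structures from the template pool, assigns each an
#' oracle pKa plus Gaussian noise, expands them into replicate groups
#' with exactly realized standard-deviation bands, and injects salt
#' forms, mixtures and inorganic records so that every curation path is
#' exercised. The returned `pka_records` carries a `truth` attribute
#' (structure-level table with template, oracle values, SD band) and an
#' `injection` attribute (counts of salts, mixtures, inorganics).
#'
#' @param spec A [fixture_spec()].
#' @return A `pka_records` data.frame with `truth` and `injection`
#'   attributes.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  pool <- fixture_pool()
  n <- spec$n_structures
  n_amph <- round(spec$pct_amphoteric * n)
  amph_pool <- pool[pool$class_type == "amphoteric", ]
  mono_pool <- pool[pool$class_type != "amphoteric", ]
  if (n_amph > nrow(amph_pool) || (n - n_amph) > nrow(mono_pool)) {
    stop("infeasible spec: template pool too small for n_structures")
  }
  local_seed(spec$seed, {
    chosen <- rbind(
      amph_pool[sample.int(nrow(amph_pool), n_amph), , drop = FALSE],
      mono_pool[sample.int(nrow(mono_pool), n - n_amph), , drop = FALSE])
    chosen <- chosen[sample.int(nrow(chosen)), , drop = FALSE]
    rownames(chosen) <- NULL
    sizes <- as.integer(names(spec$replicate_profile))
    chosen$group_size <- sample(sizes, n, replace = TRUE,
                                prob = spec$replicate_profile)
    chosen$sd_bucket <- ifelse(
      chosen$group_size == 1L, "none",
      sample(names(spec$sd_profile), n, replace = TRUE,
             prob = spec$sd_profile))
    draw_sd <- function(bucket) {
      switch(bucket,
             none = 0,
             low = stats::runif(1, 0.05, 0.8),
             mid = stats::runif(1, 1.1, 1.9),
             high = stats::runif(1, 2.2, 3.5))
    }
    chosen$target_sd <- vapply(chosen$sd_bucket, draw_sd, numeric(1))

    methods <- c("titration", "spectrophotometry",
                 "capillary electrophoresis", NA_character_)
    smiles <- character(0); pka <- numeric(0); cls <- character(0)
    meth <- character(0); sid <- integer(0)
    for (i in seq_len(n)) {
      row <- chosen[i, ]
      for (class_i in c("acidic", "basic")) {
        truth <- if (class_i == "acidic") row$oracle_acidic else row$oracle_basic
        if (is.na(truth)) next
        center <- truth + stats::rnorm(1, 0, spec$noise_sd)
        lohi <- if (class_i == "acidic") c(0, 14) else c(-2, 12)
        # keep the whole replicate fan inside the modeled range so the
        # realized group SD stays exactly on target
        margin <- 1.2 * row$target_sd
        center <- clamp(center, lohi[1] + margin, lohi[2] - margin)
        vals <- replicate_values(center, row$group_size, row$target_sd)
        smiles <- c(smiles, rep(row$smiles, length(vals)))
        pka <- c(pka, vals)
        cls <- c(cls, rep(class_i, length(vals)))
        meth <- c(meth, sample(methods, length(vals), replace = TRUE))
        sid <- c(sid, rep(i, length(vals)))
      }
    }

    # salt forms: acid records as sodium carboxylate, others co-crystal
    n_salt <- round(spec$pct_salts * length(smiles))
    salt_idx <- if (n_salt > 0) sample.int(length(smiles), n_salt) else integer(0)
    for (j in salt_idx) {
      s <- smiles[j]
      smiles[j] <- if (grepl("OC(=O)", s, fixed = TRUE)) {
        paste0(sub("OC(=O)", "[O-]C(=O)", s, fixed = TRUE), ".[Na+]")
      } else if (cls[j] == "basic") {
        paste0(s, ".Cl")
      } else {
        paste0(s, ".[Na+]")
      }
    }

    # mixtures: two distinct organic parents in one record
    n_mix <- round(spec$pct_mixtures * n)
    if (n_mix > 0) {
      for (m in seq_len(n_mix)) {
        pair <- pool[sample.int(nrow(pool), 2L), ]
        smiles <- c(smiles, paste0(pair$smiles[1], ".", pair$smiles[2]))
        pka <- c(pka, stats::runif(1, 2, 10))
        cls <- c(cls, sample(c("acidic", "basic"), 1L))
        meth <- c(meth, NA_character_)
        sid <- c(sid, NA_integer_)
      }
    }
    # inorganic records
    n_inorg <- round(spec$pct_inorganics * n)
    if (n_inorg > 0) {
      pick <- sample.int(nrow(.fixture_inorganics), n_inorg, replace = TRUE)
      smiles <- c(smiles, .fixture_inorganics$smiles[pick])
      pka <- c(pka, .fixture_inorganics$pka[pick])
      cls <- c(cls, .fixture_inorganics$class[pick])
      meth <- c(meth, rep(NA_character_, n_inorg))
      sid <- c(sid, rep(NA_integer_, n_inorg))
    }

    ord <- sample.int(length(smiles))
    rec <- pka_records(smiles[ord], pka[ord], cls[ord], method = meth[ord])
    rec$structure_id <- sid[ord]
    attr(rec, "truth") <- chosen
    attr(rec, "injection") <- list(n_salt_records = n_salt,
                                   n_mixtures = n_mix,
                                   n_inorganics = n_inorg)
    attr(rec, "spec") <- spec
    rec
  })
}
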