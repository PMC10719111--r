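# Rule-based neurotransmitter / neuropeptide assignment and region-level
# excitatory-inhibitory composition with exact binomial confidence intervals.

#' Default neurochemical assignment rules
#'
#' Nine neurotransmitter identities defined as conjunctions/disjunctions of
#' detection fractions at the nonzero threshold `nz` = 0.35, neuropeptide
#' ligand thresholds (fraction >= 0.3 and mean >= 0.5 counts/cell; the four
#' high-contamination peptides Oxt, Avp, Pmch and Agrp require fraction >=
#' 0.8 and mean >= 5), and receptor thresholds (fraction >= 0.2, mean >=
#' 0.5).
#'
#' @return list of thresholds and gene symbols, editable before assignment.
#' @export
neurochem_rules <- function() {
  list(
    nz = 0.35,
    nt = list(
      VGLUT1 = list(any = list("Slc17a7")),
      VGLUT2 = list(any = list("Slc17a6")),
      VGLUT3 = list(any = list("Slc17a8")),
      GABA = list(all = list(c("Gad1", "Gad2"), "Slc32a1")),
      GLY = list(all = list(c("Gad1", "Gad2"), c("Slc6a5", "Slc6a9"))),
      CHOL = list(all = list("Slc18a3", "Chat")),
      DOP = list(any = list("Slc6a3")),
      NOR = list(any = list(c("Pnmt", "Dbh"))),
      SER = list(any = list(c("Slc6a4", "Tph2")))
    ),
    excitatory = c("VGLUT1", "VGLUT2", "VGLUT3"),
    inhibitory = c("GABA", "GLY"),
    np = list(frac = 0.3, mean = 0.5,
              special = c("Oxt", "Avp", "Pmch", "Agrp"),
              special_frac = 0.8, special_mean = 5),
    npr = list(frac = 0.2, mean = 0.5)
  )
}

#' Assign neurotransmitter identities to cell types
#'
#' Every rule whose gene conditions are met at the nonzero threshold adds its
#' identity (multi-label); types satisfying no rule are flagged unresolved.
#' A disjunctive gene group (e.g. Gad1|Gad2) is satisfied when any member
#' reaches the threshold; conjunctive rule clauses must all hold.
#'
#' @param fractions type x gene matrix of nonzero fractions.
#' @param rules from [neurochem_rules()].
#' @return data frame: `type`, `nt` (";"-collapsed identities), `ei_class`
#'   (`inhibitory` whenever GABA or GLY is present, else `excitatory` for any
#'   VGLUT, else `neither`), `unresolved`.
#' @export
assign_neurotransmitters <- function(fractions, rules = neurochem_rules()) {
  fractions <- as.matrix(fractions)
  needed <- unique(unlist(lapply(rules$nt, function(r) unlist(r))))
  missing <- setdiff(needed, colnames(fractions))
  if (length(missing))
    stop("rule genes missing from fractions: ", paste(missing, collapse = ", "))
  nz <- rules$nz
  clause_ok <- function(t, genes) any(fractions[t, genes] >= nz)
  rows <- lapply(rownames(fractions), function(t) {
    hits <- names(rules$nt)[vapply(rules$nt, function(r) {
      clauses <- if (!is.null(r$all)) r$all else r$any
      all(vapply(clauses, function(cl) clause_ok(t, cl), FALSE))
    }, FALSE)]
    inh <- any(hits %in% rules$inhibitory)
    exc <- any(hits %in% rules$excitatory)
    data.frame(type = t, nt = paste(hits, collapse = ";"),
               ei_class = if (inh) "inhibitory" else
                 if (exc) "excitatory" else "neither",
               unresolved = length(hits) == 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign neuropeptide ligand and receptor identities to cell types
#'
#' @param fractions,means type x gene matrices of nonzero fractions and mean
#'   raw counts per cell.
#' @param np_genes,npr_genes neuropeptide ligand / receptor gene symbols
#'   present in the matrices.
#' @param rules from [neurochem_rules()].
#' @return data frame: `type`, `np` and `npr` (";"-collapsed gene sets).
#' @export
assign_neuropeptides <- function(fractions, means, np_genes, npr_genes,
                                 rules = neurochem_rules()) {
  fractions <- as.matrix(fractions); means <- as.matrix(means)
  np_genes <- intersect(np_genes, colnames(fractions))
  npr_genes <- intersect(npr_genes, colnames(fractions))
  rows <- lapply(rownames(fractions), function(t) {
    np_hit <- vapply(np_genes, function(g) {
      if (g %in% rules$np$special)
        fractions[t, g] >= rules$np$special_frac &&
          means[t, g] >= rules$np$special_mean
      else
        fractions[t, g] >= rules$np$frac && means[t, g] >= rules$np$mean
    }, FALSE)
    npr_hit <- vapply(npr_genes, function(g)
      fractions[t, g] >= rules$npr$frac && means[t, g] >= rules$npr$mean,
      FALSE)
    data.frame(type = t, np = paste(np_genes[np_hit], collapse = ";"),
               npr = paste(npr_genes[npr_hit], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param x successes, `n` trials, `conf` coverage (default 0.95).
#' @param n number of trials.
#' @param conf confidence level.
#' @return numeric vector `c(lower, upper)`.
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  stopifnot(x >= 0, x <= n, n >= 1)
  a <- (1 - conf) / 2
  lower <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Region-level inhibitory fraction with exact binomial intervals
#'
#' A bead counts as inhibitory (excitatory) when it is confidently mapped to
#' an inhibitory (excitatory) type that is also one of the bead's top-two
#' ranked types, i.e. a member of its best-fitting pair. Types labelled both
#' are inhibitory. The reported fraction is `#I / (#I + #E)` with an exact
#' 95% interval; regions with fewer than `min_beads` counted beads are
#' flagged excluded.
#'
#' @param mapping a `bead_mapping`.
#' @param chemistry data frame from [assign_neurotransmitters()].
#' @param min_beads exclusion threshold (default 5).
#' @param conf interval coverage (default 0.95).
#' @return data frame per region: `n_inh`, `n_exc`, `fraction`, `ci_lo`,
#'   `ci_hi`, `excluded`.
#' @export
region_ei_fraction <- function(mapping, chemistry, min_beads = 5,
                               conf = 0.95) {
  ei <- stats::setNames(chemistry$ei_class, chemistry$type)
  bb <- mapping$beads[mapping$beads$eligible, , drop = FALSE]
  conf_tab <- mapping$confidence[mapping$confidence$confident, , drop = FALSE]
  rows <- lapply(unique(bb$region), function(r) {
    sub <- bb[bb$region == r, , drop = FALSE]
    n_i <- 0L; n_e <- 0L
    for (j in seq_len(nrow(sub))) {
      top2 <- c(sub$type_a[j], sub$type_b[j])
      ct <- conf_tab$type[conf_tab$bead_id == sub$bead_id[j]]
      hit <- intersect(ct, top2)
      if (length(hit) == 0) next
      cls <- ei[hit]
      if (any(cls == "inhibitory", na.rm = TRUE)) n_i <- n_i + 1L
      else if (any(cls == "excitatory", na.rm = TRUE)) n_e <- n_e + 1L
    }
    tot <- n_i + n_e
    ci <- if (tot >= 1) clopper_pearson(n_i, tot, conf) else c(NA_real_, NA_real_)
    data.frame(region = r, n_inh = n_i, n_exc = n_e,
               fraction = if (tot > 0) n_i / tot else NA_real_,
               ci_lo = ci[1], ci_hi = ci[2],
               excluded = tot < min_beads, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
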