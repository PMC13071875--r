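# Post-screen hit curation: calculated logP window, PAINS-style substructure
# flags from a packaged SMARTS list, and Tanimoto max-min diversity
# selection.  SMILES handling, the additive logP model, SMARTS matching and
# path fingerprints are delegated to OpenBabel via ChemmineR/ChemmineOB.

.smiles_to_sdfset <- function(smiles) {
  if (is.null(names(smiles))) names(smiles) <- paste0("cmp", seq_along(smiles))
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e) stop("unparseable SMILES: ",
                                           conditionMessage(e)))
  sdf
}

#' Calculated logP (additive atom-contribution estimate)
#'
#' Wildman-Crippen-style additive octanol/water partition estimate computed
#' by OpenBabel's logP model.  Deterministic for a given SMILES.
#'
#' @param smiles character vector of SMILES strings.
#' @return numeric vector of cLogP values.
#' @export
compute_clogp <- function(smiles) {
  vapply(smiles, function(smi) {
    res <- tryCatch(
      ChemmineOB::forEachMol("SMILES", smi,
                             function(m) ChemmineOB::prop_OB(m)),
      error = function(e) NULL)
    if (is.null(res) || length(res) == 0L || is.null(res[[1]]$logP))
      stop("unparseable SMILES: ", smi)
    as.numeric(res[[1]]$logP)
  }, 0, USE.NAMES = FALSE)
}

#' Load a PAINS-style SMARTS filter list
#'
#' Reads a tab-separated file with columns `name`, `smarts`, `source` and
#' validates every SMARTS against a probe molecule at load time, so a bad
#' pattern is a configuration error here rather than a match-time failure.
#' The packaged default is a curated set of classic pan-assay interference
#' motifs (quinones, catechols, rhodanines, and related frequent hitters).
#'
#' @param path filter file path; default is the packaged set.
#' @return data frame of class `FilterSpec` with `name`, `smarts`, `source`.
#' @export
load_pains_filters <- function(path = system.file("extdata",
                                                  "pains_smarts.tsv",
                                                  package = "nfyscreen")) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]  # '#' is meaningful inside SMARTS
  f <- utils::read.delim(textConnection(lines), stringsAsFactors = FALSE)
  stopifnot(all(c("name", "smarts", "source") %in% names(f)))
  probe <- .smiles_to_sdfset(c(probe = "c1ccccc1"))
  for (i in seq_len(nrow(f))) {
    ok <- tryCatch({
      ChemmineR::smartsSearchOB(probe, f$smarts[i]); TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("invalid SMARTS in filter '", f$name[i], "': ", f$smarts[i])
  }
  class(f) <- c("FilterSpec", class(f))
  f
}

#' Screen a molecule against PAINS-style substructure filters
#'
#' @param smiles a single SMILES string.
#' @param filters a filter table from [load_pains_filters()] (or any data
#'   frame with `name` and `smarts`).
#' @return character vector of matched filter names; empty means pass.
#' @export
pains_screen <- function(smiles, filters = load_pains_filters()) {
  stopifnot(length(smiles) == 1)
  if (nrow(filters) == 0L) return(character(0))
  sdf <- .smiles_to_sdfset(c(query = smiles))
  if (!ChemmineR::validSDF(sdf)) return(character(0))  # < 2 atoms: no motif can match
  hit <- vapply(filters$smarts, function(sm)
    as.numeric(ChemmineR::smartsSearchOB(sdf, sm, uniqueMatches = FALSE)) > 0,
    TRUE, USE.NAMES = FALSE)
  filters$name[hit]
}

#' Path fingerprints for a set of SMILES
#'
#' OpenBabel FP2 linear-path fingerprints (1024 bits), the basis of the
#' Tanimoto diversity metric.
#'
#' @param smiles named character vector of SMILES.
#' @return 0/1 matrix, one row per molecule.
#' @export
fingerprints <- function(smiles) {
  sdf <- .smiles_to_sdfset(smiles)
  m <- ChemmineR::as.matrix(ChemmineR::fingerprintOB(sdf, "FP2"))
  rownames(m) <- names(smiles)
  m
}

.tanimoto_dist <- function(fp) {
  inter <- fp %*% t(fp)
  n_on <- rowSums(fp)
  uni <- outer(n_on, n_on, "+") - inter
  sim <- ifelse(uni > 0, inter / uni, 1)
  1 - sim
}

#' Greedy max-min diversity selection
#'
#' Seeds with the best-scoring compound, then repeatedly adds the compound
#' whose minimum Tanimoto distance to the already-selected set is largest.
#' Ties are broken by lowest score, then lexicographic compound id, so the
#' selection is deterministic.
#'
#' @param records data frame with `compound_id`, `smiles`, `best_score`.
#' @param k number of compounds to select, 1 <= k <= nrow(records).
#' @return the selected rows, in selection order, with a `selected` column.
#' @export
diversity_select <- function(records, k) {
  stopifnot(all(c("compound_id", "smiles", "best_score") %in% names(records)))
  n <- nrow(records)
  if (k <= 0) stop("k must be positive")
  if (k > n) stop("k exceeds the number of records")
  fp <- fingerprints(stats::setNames(records$smiles, records$compound_id))
  D <- .tanimoto_dist(fp)
  ord0 <- order(records$best_score, records$compound_id)
  sel <- ord0[1L]
  while (length(sel) < k) {
    cand <- setdiff(seq_len(n), sel)
    min_d <- apply(D[cand, sel, drop = FALSE], 1, min)
    # max-min, ties by lowest score then id
    pick <- cand[order(-min_d, records$best_score[cand],
                       records$compound_id[cand])[1L]]
    sel <- c(sel, pick)
  }
  out <- records[sel, , drop = FALSE]
  out$selected <- TRUE
  rownames(out) <- NULL
  out
}

#' Triage a ranked screen table
#'
#' Applies the cLogP window and the PAINS screen to a ranked docking table
#' and optionally runs diversity selection on the survivors.  The cLogP
#' window has no default: it is a required choice.
#'
#' @param ranked data frame with `compound_id`, `smiles`, `total` (score).
#' @param clogp_range numeric length-2 inclusive cLogP window.
#' @param filters PAINS filter table (default: packaged set).
#' @param select_k optional diversity-selection size applied to survivors.
#' @return data frame of class `CompoundRecord` with `clogp`, `pains_flags`
#'   (comma-joined), `pass_clogp`, `pass_pains`, `selected`.
#' @export
triage_hits <- function(ranked, clogp_range, filters = load_pains_filters(),
                        select_k = NULL) {
  stopifnot(all(c("compound_id", "smiles", "total") %in% names(ranked)),
            length(clogp_range) == 2, clogp_range[1] <= clogp_range[2])
  out <- ranked
  out$best_score <- ranked$total
  out$clogp <- compute_clogp(ranked$smiles)
  flags <- lapply(ranked$smiles, pains_screen, filters = filters)
  out$pains_flags <- vapply(flags, paste, "", collapse = ",")
  out$pass_clogp <- out$clogp >= clogp_range[1] & out$clogp <= clogp_range[2]
  out$pass_pains <- vapply(flags, length, 0L) == 0L
  out$selected <- FALSE
  if (!is.null(select_k)) {
    surv <- out[out$pass_clogp & out$pass_pains, , drop = FALSE]
    if (nrow(surv) >= 1) {
      kk <- min(select_k, nrow(surv))
      chosen <- diversity_select(surv, kk)$compound_id
      out$selected <- out$compound_id %in% chosen
    }
  }
  class(out) <- c("CompoundRecord", class(out))
  out
}
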