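#' @title Membrane composition tables
#' @description Headgroup composition tables and deterministic lipid-count
#'   allocation for patch building. Two built-in tables reproduce published
#'   phospholipid headgroup ratios: a jojoba-seed-like membrane
#'   (PC:PE:PI:PG = 45:38:10:7) and a *Nicotiana tabacum* leaf membrane
#'   (PC:PE:PA:PG:PI:PS = 60:59:37:26:15:3).
#' @name composition
NULL

HEADGROUP_CODES <- c("PC", "PE", "PI", "PG", "PA", "PS")

#' Build a membrane composition table
#'
#' @param name table name.
#' @param headgroups character vector of headgroup codes (PC, PE, PI, PG,
#'   PA, PS); order is preserved and used for allocation tie-breaks.
#' @param parts nonnegative ratio parts, one per headgroup.
#' @return data frame of class `composition_table` with columns `headgroup`,
#'   `parts`, `fraction` (parts normalized to sum 1).
#' @export
composition_table <- function(name, headgroups, parts) {
  stopifnot(length(headgroups) == length(parts), length(parts) > 0L)
  bad <- setdiff(headgroups, HEADGROUP_CODES)
  if (length(bad) > 0L)
    stop("unknown headgroup code(s): ", paste(bad, collapse = ", "))
  if (any(parts < 0)) stop("ratio parts must be nonnegative")
  if (sum(parts) <= 0) stop("ratio parts must not all be zero")
  tab <- data.frame(headgroup = as.character(headgroups),
                    parts = as.numeric(parts),
                    fraction = parts / sum(parts),
                    stringsAsFactors = FALSE)
  attr(tab, "name") <- name
  class(tab) <- c("composition_table", "data.frame")
  tab
}

#' Built-in composition tables
#'
#' @param name `"jojoba"` (PC:PE:PI:PG = 45:38:10:7) or `"tabacum"`
#'   (PC:PE:PA:PG:PI:PS = 60:59:37:26:15:3).
#' @return A [composition_table()].
#' @export
builtin_composition <- function(name = c("jojoba", "tabacum")) {
  name <- match.arg(name)
  switch(name,
    jojoba = composition_table("jojoba",
      c("PC", "PE", "PI", "PG"), c(45, 38, 10, 7)),
    tabacum = composition_table("tabacum",
      c("PC", "PE", "PA", "PG", "PI", "PS"), c(60, 59, 37, 26, 15, 3)))
}

#' Allocate integer lipid counts from a composition table
#'
#' Largest-remainder (Hare) allocation: each species gets
#' `floor(fraction * n)` lipids, then the shortfall is distributed one by
#' one to the largest fractional remainders, ties broken by listed order.
#' Totals are conserved exactly.
#'
#' @param table a [composition_table()].
#' @param n_lipids total lipids to allocate (per leaflet, typically).
#' @return named integer vector of counts summing to `n_lipids`.
#' @export
allocate_counts <- function(table, n_lipids) {
  if (n_lipids <= 0L) stop("n_lipids must be positive")
  n_nonzero <- sum(table$fraction > 0)
  if (n_lipids < n_nonzero)
    stop(sprintf("patch too small: %d lipids cannot host %d species",
                 n_lipids, n_nonzero))
  quota <- table$fraction * n_lipids
  counts <- floor(quota)
  shortfall <- n_lipids - sum(counts)
  if (shortfall > 0L) {
    rem <- quota - counts
    # order(-rem, listed index): ties go to the earlier-listed species
    extra <- order(-rem, seq_along(rem))[seq_len(shortfall)]
    counts[extra] <- counts[extra] + 1L
  }
  stats::setNames(as.integer(counts), table$headgroup)
}

#' Full factorial grid of binding scenarios
#'
#' Cartesian product of protein labels, composition tables, membrane kinds
#' and orientation indices, in deterministic order with orientation varying
#' fastest. Six orientations x 2 proteins x 2 compositions x 3 membrane
#' kinds gives the canonical 72-system grid.
#'
#' @param proteins character vector of protein labels.
#' @param compositions list of [composition_table()]s (or names for
#'   [builtin_composition()]).
#' @param membrane_kinds subset of `c("bilayer","we_monolayer","tag_monolayer")`.
#' @param orientations integer orientation indices in 1..6.
#' @param ... further arguments passed to every [scenario_config()].
#' @return list of [scenario_config()] objects; the grid (one row per
#'   scenario) is attached as attribute `"grid"`.
#' @export
scenario_grid <- function(proteins, compositions, membrane_kinds,
                          orientations = 1:6, ...) {
  stopifnot(length(proteins) > 0L, length(compositions) > 0L,
            length(membrane_kinds) > 0L, length(orientations) > 0L)
  if (is.character(compositions)) compositions <- as.list(compositions)
  comp_names <- vapply(compositions, function(x)
    if (is.character(x)) x else attr(x, "name") %||% "custom", character(1L))
  grid <- expand.grid(orientation = orientations,
                      protein = proteins,
                      composition = comp_names,
                      membrane_kind = membrane_kinds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  configs <- lapply(seq_len(nrow(grid)), function(i) {
    comp <- compositions[[match(grid$composition[i], comp_names)]]
    if (is.character(comp)) comp <- builtin_composition(comp)
    scenario_config(membrane_kind = grid$membrane_kind[i],
                    composition = comp,
                    orientation_index = grid$orientation[i],
                    protein_label = grid$protein[i], ...)
  })
  attr(configs, "grid") <- grid
  configs
}
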