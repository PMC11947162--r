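#' Normalize lipidomics peak areas to internal standards
#'
#' The normalized ratio of a species is its raw peak area divided by the
#' matched internal-standard area, and — for oxidized glycerophospholipids —
#' additionally by the protein content of the sample (per ug). Fatty-acid
#' panels omit the protein step (`per_protein = FALSE`).
#'
#' @param table a `lipid_table` (or any data frame) with columns `species`,
#'   `condition`, `replicate`, `area`, `is_area`, and `protein_ug` when
#'   `per_protein`.
#' @param per_protein divide by protein content?
#' @return the input with a `normalized` column appended.
#' @examples
#' tab <- data.frame(species = "PC", condition = "control", replicate = 1,
#'                   area = 50, is_area = 100, protein_ug = 10)
#' normalize_areas(tab)$normalized       # 0.05
#' normalize_areas(tab, per_protein = FALSE)$normalized  # 0.5
#' @export
normalize_areas <- function(table, per_protein = TRUE) {
  need <- c("species", "condition", "replicate", "area", "is_area")
  if (per_protein) need <- c(need, "protein_ug")
  miss <- setdiff(need, names(table))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  bad <- which(!is.finite(table$is_area) | table$is_area <= 0)
  if (length(bad))
    stopf("non-positive internal-standard area in row(s) %s",
          paste(head(bad, 5L), collapse = ", "))
  if (any(!is.finite(table$area) | table$area <= 0))
    stopf("non-positive peak area in row(s) %s",
          paste(head(which(table$area <= 0), 5L), collapse = ", "))
  norm <- table$area / table$is_area
  if (per_protein) {
    badp <- which(!is.finite(table$protein_ug) | table$protein_ug <= 0)
    if (length(badp))
      stopf("non-positive protein content in row(s) %s",
            paste(head(badp, 5L), collapse = ", "))
    norm <- norm / table$protein_ug
  }
  table$normalized <- norm
  table
}

#' Illuminated-versus-control fold changes per species
#'
#' For each species and replicate, the fold change is the normalized ratio
#' under illumination divided by the replicate-matched non-illuminated
#' control; the per-species summary is the arithmetic mean over replicates
#' (geometric mean available via `mean_type`). Every species must have a
#' matched illuminated/control pair in every replicate.
#'
#' @param normalized output of [normalize_areas()].
#' @param mean_type `"arithmetic"` (default) or `"geometric"`.
#' @return a `fold_change_table`: list with `per_replicate` (data frame
#'   `species`, `replicate`, `fold_change`) and `summary` (data frame
#'   `species`, `mean_fc`).
#' @export
fold_changes <- function(normalized, mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  if (!"normalized" %in% names(normalized))
    stopf("run normalize_areas() first")
  sp <- unique(normalized$species)
  reps <- sort(unique(normalized$replicate))
  rows <- list()
  for (s in sp) for (r in reps) {
    ill <- normalized$normalized[normalized$species == s &
                                   normalized$replicate == r &
                                   normalized$condition == "illuminated"]
    ctl <- normalized$normalized[normalized$species == s &
                                   normalized$replicate == r &
                                   normalized$condition == "control"]
    if (length(ill) != 1L || length(ctl) != 1L)
      stopf("species `%s`, replicate %s: need exactly one illuminated and one control entry",
            s, r)
    if (ctl == 0) stopf("species `%s`, replicate %s: zero control ratio", s, r)
    rows[[length(rows) + 1L]] <-
      data.frame(species = s, replicate = r, fold_change = ill / ctl,
                 stringsAsFactors = FALSE)
  }
  per_rep <- do.call(rbind, rows)
  agg <- vapply(sp, function(s) {
    fc <- per_rep$fold_change[per_rep$species == s]
    if (mean_type == "arithmetic") mean(fc) else exp(mean(log(fc)))
  }, numeric(1))
  structure(list(per_replicate = per_rep,
                 summary = data.frame(species = sp, mean_fc = unname(agg),
                                      stringsAsFactors = FALSE),
                 mean_type = mean_type),
            class = "fold_change_table")
}
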