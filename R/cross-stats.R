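#' Build a genotype x tail-phenotype count table
#'
#' Rows are genotypes; columns the four tail phenotype categories used in
#' mouse crosses (`no_tail`, `short_tail`, `kinked_tail`, `long_tail`).
#' An optional `total` column allows tables whose category counts do not
#' exhaust the total; when omitted the row total is the category sum.
#' `runt_deaths` (perinatal deaths recorded inside the no-tail cells) is
#' carried as a supplementary column and never enters phenotype totals.
#'
#' @param df data.frame with columns `genotype`, `no_tail`, `short_tail`,
#'   `kinked_tail`, `long_tail`, and optionally `total`, `breeding_type`,
#'   `runt_deaths`.
#' @return A `phenotype_table` data.frame.
#' @export
phenotype_table <- function(df) {
  cats <- c("no_tail", "short_tail", "kinked_tail", "long_tail")
  stopifnot(all(c("genotype", cats) %in% names(df)))
  for (c in cats) df[[c]] <- as.integer(df[[c]])
  if (any(unlist(df[cats]) < 0L)) stop("negative phenotype counts")
  if (!"total" %in% names(df)) df$total <- rowSums(df[cats])
  df$total <- as.integer(df$total)
  if (any(df$total < rowSums(df[cats])))
    stop("row total smaller than the sum of category counts")
  if (!"breeding_type" %in% names(df)) df$breeding_type <- NA_character_
  if (!"runt_deaths" %in% names(df)) df$runt_deaths <- 0L
  class(df) <- c("phenotype_table", class(df))
  df
}

#' Read a phenotype count table from TSV
#' @param path Path to a TSV with the [phenotype_table()] columns.
#' @return A `phenotype_table`.
#' @export
read_phenotype_table <- function(path) {
  phenotype_table(utils::read.table(path, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE))
}

#' Affected and total counts for a genotype
#'
#' "Affected" means any tail phenotype: `no_tail + short_tail + kinked_tail`
#' (long-tailed animals are unaffected). Rows of the same genotype (e.g.
#' across breeding types) are pooled.
#'
#' @param table A [phenotype_table()].
#' @param genotype Genotype label present in the table.
#' @return Named integer vector `c(affected, total)`.
#' @export
aggregate_phenotypes <- function(table, genotype) {
  rows <- table[table$genotype == genotype, , drop = FALSE]
  if (nrow(rows) == 0L) stop("genotype '", genotype, "' not in table")
  c(affected = sum(rows$no_tail + rows$short_tail + rows$kinked_tail),
    total = sum(rows$total))
}

#' Penetrance with an exact binomial confidence interval
#'
#' Point estimate `affected / total` with the Clopper-Pearson two-sided
#' interval (exact, rather than a normal approximation, because cross tables
#' routinely contain 0% and 100% cells).
#'
#' @param affected,total Non-negative integers, `affected <= total`.
#' @param conf_level Confidence level, default 0.95.
#' @return List with `estimate`, `lower`, `upper`, `affected`, `total`;
#'   all `NA` when `total` is 0.
#' @export
penetrance <- function(affected, total, conf_level = 0.95) {
  affected <- as.integer(affected); total <- as.integer(total)
  if (affected < 0L || total < 0L) stop("counts must be non-negative")
  if (affected > total) stop("affected exceeds total")
  if (total == 0L)
    return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                affected = 0L, total = 0L))
  bt <- stats::binom.test(affected, total, conf.level = conf_level)
  list(estimate = affected / total,
       lower = bt$conf.int[1], upper = bt$conf.int[2],
       affected = affected, total = total)
}

parse_genotype <- function(g) {
  al <- strsplit(g, "/", fixed = TRUE)[[1]]
  if (length(al) != 2L) stop("genotype '", g, "' is not biallelic (allele/allele)")
  al
}

genotype_label <- function(a1, a2) {
  # mutant alleles first, wild-type '+' last; alphabetical otherwise
  al <- c(a1, a2)
  al <- al[order(al == "+", al)]
  paste(al, collapse = "/")
}

#' Mendelian expected offspring proportions of a cross
#'
#' Punnett-square proportions for two biallelic parents: het x het gives
#' 1:2:1, het x hom 1:1, hom x wild-type all heterozygous. Proportions are
#' the zygotic expectation, before any viability selection — deviation from
#' them is what [ratio_test()] measures.
#'
#' @param parent1,parent2 Genotype strings `"allele1/allele2"`, e.g.
#'   `"dexon6/+"`.
#' @return Named numeric vector of offspring genotype proportions
#'   (summing to 1).
#' @export
expected_offspring <- function(parent1, parent2) {
  g1 <- parse_genotype(parent1); g2 <- parse_genotype(parent2)
  combos <- expand.grid(a = g1, b = g2, stringsAsFactors = FALSE)
  labels <- mapply(genotype_label, combos$a, combos$b)
  tab <- table(labels) / nrow(combos)
  out <- as.numeric(tab)
  names(out) <- names(tab)
  sort(out, decreasing = TRUE)
}

#' Chi-square goodness-of-fit of observed counts to expected proportions
#'
#' Pearson's statistic `sum((O - E)^2 / E)` with `E = proportion * total`
#' and `df = categories - 1` (via `stats::chisq.test`). Used to quantify
#' departures from Mendelian ratios, e.g. missing homozygotes or
#' under-represented compound heterozygotes.
#'
#' @param observed Named integer vector of category counts (>= 2 categories).
#' @param expected Named numeric vector of proportions summing to 1, in the
#'   same category order (names are matched when present on both).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
ratio_test <- function(observed, expected) {
  if (length(observed) < 2L) stop("need at least two categories")
  if (length(observed) != length(expected))
    stop("observed and expected lengths differ")
  if (!is.null(names(observed)) && !is.null(names(expected))) {
    if (!setequal(names(observed), names(expected)))
      stop("category names differ between observed and expected")
    expected <- expected[names(observed)]
  }
  if (abs(sum(expected) - 1) > 1e-8) stop("expected proportions must sum to 1")
  if (any(expected <= 0)) stop("expected proportion of zero")
  ct <- suppressWarnings(stats::chisq.test(as.integer(observed), p = expected))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}
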