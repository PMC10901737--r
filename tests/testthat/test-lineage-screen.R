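p8 <- toy_partition()

col8 <- function(ing, out1, out2) {
  v <- c(rep(ing, 6), out1, out2)
  names(v) <- c(p8$ingroup, p8$outgroups)
  v
}

test_that("classify_column applies the presence/absence rules", {
  cfg <- variant_call_config()
  expect_equal(classify_column(col8("A", "A", "A"), p8, cfg)$verdict, "none")
  v <- classify_column(col8("A", "G", "G"), p8, cfg)
  expect_equal(v$verdict, "snv")
  expect_equal(v$ingroup_allele, "A")
  expect_false(v$ambiguous_outgroup)
  # outgroups disagreeing with each other: called, but flagged ambiguous
  v2 <- classify_column(col8("A", "A", "G"), p8, cfg)
  expect_equal(v2$verdict, "snv")
  expect_true(v2$ambiguous_outgroup)
  expect_equal(unname(v2$outgroup_support), c("matches", "differs"))
  # under both-differ the same column is not called
  cfg_b <- variant_call_config(snv_outgroup_rule = "both-differ")
  expect_equal(classify_column(col8("A", "A", "G"), p8, cfg_b)$verdict, "none")
  # deletion: ingroup all gapped, both outgroups carry bases
  v3 <- classify_column(col8("-", "C", "C"), p8, cfg)
  expect_equal(v3$verdict, "del_site")
  expect_equal(classify_column(col8("-", "C", "-"), p8, cfg)$verdict, "none")
  # insertion: ingroup bases, at least one outgroup gapped (any-absent)
  expect_equal(classify_column(col8("T", "-", "T"), p8, cfg)$verdict, "ins_site")
  cfg_i <- variant_call_config(ins_outgroup_rule = "both-absent")
  expect_equal(classify_column(col8("T", "-", "T"), p8, cfg_i)$verdict, "none")
  expect_equal(classify_column(col8("T", "-", "-"), p8, cfg_i)$verdict, "ins_site")
  # N in a decisive species suppresses the call
  expect_equal(classify_column(col8("A", "N", "G"), p8, cfg)$verdict, "none")
  ncol_ <- col8("A", "G", "G"); ncol_["gorGor5"] <- "N"
  expect_equal(classify_column(ncol_, p8, cfg)$verdict, "none")
  # incomplete ingroup -> none by default
  short <- col8("A", "G", "G")[-3]
  expect_equal(classify_column(short, p8, cfg)$verdict, "none")
})

test_that("classify_column matches the brute-force oracle on random columns", {
  cfgs <- list(variant_call_config(),
               variant_call_config(snv_outgroup_rule = "both-differ",
                                   ins_outgroup_rule = "both-absent"))
  withr::with_seed(77, {
    for (cfg in cfgs) {
      for (i in 1:1500) {
        cl <- random_column(p8)
        got <- classify_column(cl, p8, cfg)
        want <- oracle_column_verdict(cl, p8,
                                      snv_rule = cfg$snv_outgroup_rule,
                                      ins_rule = cfg$ins_outgroup_rule)
        expect_equal(got$verdict, want)
        if (got$verdict != "none") {
          sup <- got$outgroup_support
          expect_equal(unname(got$ambiguous_outgroup),
                       length(unique(sup)) > 1)
        }
      }
    }
  })
})

test_that("call_snvs finds exactly the planted divergent columns", {
  texts <- setNames(rep("ACGTACGTAC", 8), c(p8$ingroup, p8$outgroups))
  b <- block_from_texts(texts, start = 50L)
  expect_equal(nrow(call_snvs(b, p8)), 0)
  # plant a divergent column at offset 3 (ingroup T, outgroups A)
  t2 <- texts
  for (s in p8$ingroup) substr(t2[s], 4, 4) <- "T"
  for (s in p8$outgroups) substr(t2[s], 4, 4) <- "A"
  v <- call_snvs(block_from_texts(t2, start = 50L), p8)
  expect_equal(nrow(v), 1)
  expect_equal(v$start, 53L)
  expect_equal(v$ingroup_allele, "T")
  expect_error(call_snvs(b, species_partition(ingroup = c("xx1", "hg38"),
                                              reference = "xx1")), "absent")
})

test_that("indel runs merge maximally and split on outgroup-pattern changes", {
  # 3 consecutive ins columns (both outgroups gapped) -> one insertion
  texts <- setNames(rep("AACCCGGTT", 8), c(p8$ingroup, p8$outgroups))
  for (s in p8$outgroups) substr(texts[s], 3, 5) <- "---"
  v <- call_indels(block_from_texts(texts, start = 10L), p8)
  expect_equal(nrow(v), 1)
  expect_equal(v$kind, "insertion")
  expect_equal(c(v$start, v$end), c(12L, 15L))
  expect_equal(v$ingroup_allele, "CCC")
  # 2 consecutive del columns -> one deletion, width-0 anchor, outgroup seg len 2
  texts <- setNames(rep("AACCGGTT", 8), c(p8$ingroup, p8$outgroups))
  for (s in p8$ingroup) substr(texts[s], 4, 5) <- "--"
  v <- call_indels(block_from_texts(texts, start = 100L), p8)
  expect_equal(nrow(v), 1)
  expect_equal(v$kind, "deletion")
  expect_equal(c(v$start, v$end), c(103L, 103L))  # anchor before next ref base
  expect_equal(v$ingroup_allele, "")
  expect_match(v$outgroup_alleles, "macNem1=CG")
  # adjacent ins columns with different absence patterns -> two insertions
  texts <- setNames(rep("AACCGGTT", 8), c(p8$ingroup, p8$outgroups))
  substr(texts["macNem1"], 3, 4) <- "--"
  substr(texts["calJac3"], 5, 6) <- "--"
  v <- call_indels(block_from_texts(texts), p8)
  expect_equal(nrow(v), 2)
  expect_true(all(v$kind == "insertion"))
  expect_true(all(v$ambiguous_outgroup))
  # min_indel_length drops short runs
  v <- call_indels(block_from_texts(texts), p8,
                   variant_call_config(min_indel_length = 3L))
  expect_equal(nrow(v), 0)
})

test_that("indel calls equal a run-length-encoding oracle on random patterns", {
  oracle_runs <- function(verdicts, patterns) {
    key <- ifelse(verdicts %in% c("ins_site", "del_site"),
                  paste(verdicts, patterns), "x")
    r <- rle(key)
    keep <- r$values != "x"
    data.frame(len = r$lengths[keep],
               kind = sub(" .*", "", r$values[keep]))
  }
  withr::with_seed(99, {
    for (rep in 1:25) {
      b <- random_block(width = sample(20:60, 1), gap_prob = 0.3)
      verdicts <- patterns <- character(block_width(b))
      m <- sapply(strsplit(b$rows$text, ""), identity)
      rownames(m) <- NULL
      mm <- t(m); rownames(mm) <- b$rows$species
      for (j in seq_len(ncol(mm))) {
        cl <- mm[, j]; names(cl) <- rownames(mm)
        verdicts[j] <- oracle_column_verdict(cl, p8)
        patterns[j] <- paste(cl[p8$outgroups] == "-", collapse = "")
      }
      want <- oracle_runs(verdicts, patterns)
      got <- call_indels(b, p8)
      expect_equal(nrow(got), nrow(want))
      if (nrow(got)) {
        got_len <- ifelse(got$kind == "insertion", got$end - got$start,
                          nchar(sub(";.*", "", sub("^[^=]*=", "",
                                                   got$outgroup_alleles))))
        expect_equal(sort(paste(got$kind,
                                ifelse(got$kind == "insertion",
                                       got$end - got$start, got_len))),
                     sort(paste(ifelse(want$kind == "ins_site", "insertion",
                                       "deletion"), want$len)))
      }
    }
  })
})

test_that("calls are invariant under block subdivision between variants", {
  sim <- simulate_alignment(400, random_planting(400, 5, 3, 3, seed = 8),
                            partition = p8, seed = 8)
  whole <- rbind(call_snvs(sim$block, p8), call_indels(sim$block, p8))
  # split at a reference coordinate between two variants
  pos <- sort(sim$truth$start)
  mid <- as.integer(floor((pos[5] + pos[6]) / 2))
  chrom <- sim$truth$chrom[1]
  left <- slice_block(sim$block, genomic_interval(chrom, 0L, mid), "hg38")
  right <- slice_block(sim$block, genomic_interval(chrom, mid, 10000L), "hg38")
  parts <- rbind(call_snvs(left, p8), call_indels(left, p8),
                 call_snvs(right, p8), call_indels(right, p8))
  cols <- c("kind", "start", "end", "ingroup_allele")
  expect_equal(parts[order(parts$start, parts$kind), cols],
               whole[order(whole$start, whole$kind), cols],
               ignore_attr = TRUE)
})

test_that("screen_genes recovers planted truth and counts by class", {
  planted <- data.frame(
    kind = c(rep("SNV", 5), rep("insertion", 2), "deletion"),
    pos = c(10L, 60L, 120L, 200L, 340L, 400L, 460L, 520L),
    length = c(1L, 1L, 1L, 1L, 1L, 4L, 2L, 3L))
  sim <- simulate_alignment(600, planted, partition = p8, seed = 12)
  genes <- data.frame(gene_id = "G1", chrom = "chrSim", start = 0L, end = 600L)
  res <- screen_genes(list(sim$block), genes, p8)
  expect_equal(res$summary$n_snv, 5)
  expect_equal(res$summary$n_insertion, 2)
  expect_equal(res$summary$n_deletion, 1)
  got <- res$variants[order(res$variants$start, res$variants$kind),
                      c("kind", "chrom", "start", "end", "ingroup_allele")]
  want <- sim$truth[order(sim$truth$start, sim$truth$kind), ]
  expect_equal(got, want, ignore_attr = TRUE)
  # conserved region -> zero counts, with a warning for the uncovered gene
  sim0 <- simulate_alignment(200, partition = p8, seed = 13)
  genes2 <- rbind(genes, data.frame(gene_id = "G2", chrom = "chrSim",
                                    start = 900000L, end = 900100L))
  expect_warning(res0 <- screen_genes(list(sim0$block), genes2, p8,
                                      variant_call_config(flank_bp = 10L)),
                 "G2")
  expect_equal(unlist(res0$summary[c("n_snv", "n_insertion", "n_deletion")]),
               c(n_snv = 0L, n_insertion = 0L, n_deletion = 0L))
})

test_that("variants shared by overlapping gene regions are counted once", {
  sim <- simulate_alignment(300, data.frame(kind = "SNV", pos = 150L,
                                            length = 1L),
                            partition = p8, seed = 14)
  genes <- data.frame(gene_id = c("GA", "GB"), chrom = "chrSim",
                      start = c(0L, 100L), end = c(200L, 300L))
  res <- screen_genes(list(sim$block), genes, p8,
                      variant_call_config(flank_bp = 50L))
  expect_equal(res$summary$n_snv, 1)                   # de-duplicated
  expect_equal(sum(res$variants$kind == "SNV"), 2)     # once per gene
  pg <- res$summary$per_gene
  expect_setequal(pg$gene_id[pg$kind == "SNV" & pg$Freq == 1], c("GA", "GB"))
})

test_that("variant tables round-trip through the TSV writer", {
  sim <- simulate_alignment(500, random_planting(500, 6, 3, 3, seed = 21),
                            partition = p8, seed = 21)
  v <- rbind(call_snvs(sim$block, p8), call_indels(sim$block, p8))
  v$gene_id <- "G1"
  f <- withr::local_tempfile(fileext = ".tsv")
  out <- write_variants(v, f)
  # POS is 1-based: SNV at 0-based 99 prints as 100
  snv1 <- v[v$kind == "SNV", ][1, ]
  expect_equal(out$POS[out$KIND == "SNV"][1] - 1L,
               sort(v$start[v$kind == "SNV"])[1])
  back <- read_variants(f)
  cols <- c("kind", "chrom", "start", "end", "ingroup_allele",
            "outgroup_alleles", "outgroup_support", "ambiguous_outgroup",
            "gene_id")
  expect_equal(back[order(back$start, back$kind), cols],
               v[order(v$start, v$kind), cols], ignore_attr = TRUE)
  # empty table -> header only
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_variants(v[0, ], f2)
  expect_equal(length(readLines(f2)), 1)
  expect_equal(nrow(read_variants(f2)), 0)
})
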