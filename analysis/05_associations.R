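#!/usr/bin/env Rscript
# Program-trait association (program burden effects with constraint-matched
# permutation nulls; regulator-burden correlations), the two-sided QQ
# table, top-hit Fisher enrichment, and TF ChIP-score annotation of the
# programs.

source("analysis/00_config.R")

truth <- read_ground_truth_json(file.path(data_dir, "truth.json"))
post <- read_burden_tsv("results/posterior.tsv")
gamma <- setNames(post$posterior_mean, post$gene)
shet <- setNames(post$shet, post$gene)

L <- as.matrix(read.table("results/loadings.tsv", header = TRUE, sep = "\t",
                          row.names = 1))
L <- L[intersect(rownames(L), names(gamma)), ]
eff <- read.table("results/effects_programs.tsv", header = TRUE, sep = "\t")

B <- matrix(NA_real_, nrow(L), ncol(L), dimnames = dimnames(L))
for (p in colnames(L)) {
  sub <- eff[eff$response == p, ]
  B[intersect(rownames(B), sub$perturbed_gene), p] <-
    sub$beta[match(intersect(rownames(B), sub$perturbed_gene),
                   sub$perturbed_gene)]
}
B <- B[rowSums(is.na(B)) == 0, ]

assoc <- associate_programs(gamma, L, B, shet, n_top = 30L,
                            n_perm = 5000L, seed = 13L)
write.table(assoc, "results/program_associations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("program associations (burden effect & regulator correlation):\n")
print(assoc, row.names = FALSE)

qq <- two_sided_qq(assoc$rbc_signed_logp)
write.table(qq, "results/association_qq.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# are planted pathway genes enriched among the top regulators of the
# strongest program? (GWAS-hit-style Fisher enrichment)
strongest <- assoc$program[which.max(abs(assoc$rbc_signed_logp))]
ranking <- setNames(eff$p_value[eff$response == colnames(L)[strongest]],
                    eff$perturbed_gene[eff$response == colnames(L)[strongest]])
hits <- intersect(names(truth$regulators), names(ranking))
enr <- top_hit_enrichment(hits, ranking, top_n = 60L,
                          background = names(ranking))
cat(sprintf("top-60 regulator enrichment of planted pathway genes: OR %.2f (%.2f-%.2f), p = %.2g\n",
            enr$odds_ratio, enr$ci95[1], enr$ci95[2], enr$p))
jsonlite::write_json(list(program = strongest, odds_ratio = enr$odds_ratio,
                          ci95 = enr$ci95, p = enr$p),
                     "results/top_hit_enrichment.json", auto_unbox = TRUE,
                     digits = NA)

# TF annotation from synthetic ChIP peaks
peaks <- read_narrowpeak(file.path(data_dir, "peaks.narrowPeak"))
tss <- read_tss_bed(file.path(data_dir, "tss.bed"))
scores <- list(`5000` = compute_chip_scores(peaks, tss, 5000),
               `50000` = compute_chip_scores(peaks, tss, 50000))
eff_gene <- read.table("results/effects_tf_genes.tsv", header = TRUE,
                       sep = "\t")
deg_dn <- lapply(split(eff_gene, eff_gene$perturbed_gene), function(d)
  d$response[d$fdr < 0.1 & d$beta < 0 & !d$self])
deg_up <- lapply(split(eff_gene, eff_gene$perturbed_gene), function(d)
  d$response[d$fdr < 0.1 & d$beta > 0 & !d$self])
cls <- classify_tf_direction(scores, deg_up, deg_dn,
                             background = rownames(L))
write.table(cls, "results/tf_direction.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("TF direction calls:\n"); print(cls, row.names = FALSE)

flagged <- cls$tf[cls$activator | cls$inhibitor]
if (length(flagged)) {
  sc_used <- do.call(rbind, lapply(flagged, function(tf)
    scores[[cls$decay[cls$tf == tf]]][tf, , drop = FALSE]))
  ann <- annotate_program_tfs(sc_used, L, n_top = 30L,
                              classified_tfs = flagged,
                              usage_effects = eff)
  write.table(ann, "results/tf_program_annotation.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("%d (program, TF) annotations written\n", nrow(ann)))
}
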