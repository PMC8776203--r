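#!/usr/bin/env Rscript
# Colocalization of classified target genes with persistent receptor
# binding sites inside TAD-scale windows (default 1 Mb, half the canonical
# 2 Mb TAD upper bound). Gene loci and peaks are synthetic: the simulated
# genes have no real coordinates, so direct targets are laid out near
# planted peaks and other genes uniformly, mimicking the expectation that
# direct targets share a TAD with a persistent binding site.
library(tctargets)

cl <- read.table("results/classification.tsv", header = TRUE, sep = "\t")
clu <- read.table("results/clusters.tsv", header = TRUE, sep = "\t")
mech <- setNames(clu$mechanism, clu$gene)

set.seed(2)
genes <- cl$gene
chrom <- sample(paste0("chr", 1:6), length(genes), replace = TRUE)
pos <- sample.int(8e7, length(genes))
# place peaks near a random half of the direct targets, plus background
direct_genes <- genes[mech[genes] == "direct"]
anchored <- sample(direct_genes, ceiling(length(direct_genes) / 2))
ai <- match(anchored, genes)
peak_start <- c(pos[ai] + sample(-8e5:8e5, length(ai), replace = TRUE),
                sample.int(8e7, 40))
peak_chrom <- c(chrom[ai], sample(paste0("chr", 1:6), 40, replace = TRUE))
peak_start <- pmax(peak_start, 1)

gene_bed <- genomic_intervals(data.frame(
  chrom = chrom, start = pos, end = pos + 2000, name = genes,
  score = 0, strand = sample(c("+", "-"), length(genes), replace = TRUE),
  stringsAsFactors = FALSE))
peak_bed <- genomic_intervals(data.frame(
  chrom = peak_chrom, start = peak_start, end = peak_start + 400,
  name = sprintf("synthetic_peak_%03d", seq_along(peak_start)),
  stringsAsFactors = FALSE))
write_bed(gene_bed, "results/target_genes.synthetic.bed")
write_bed(peak_bed, "results/persistent_sites.synthetic.bed")

coloc <- colocalize(gene_bed, peak_bed, window_bp = 1e6)
coloc$mechanism <- unname(mech[coloc$gene])
write.table(coloc, "results/colocalization.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d / %d target genes lie within 1 Mb of a persistent site\n",
            sum(coloc$within_window), nrow(coloc)))
print(round(100 * tapply(coloc$within_window, coloc$mechanism, mean), 1))
cat("Direct targets colocalize far more often -- by construction here,",
    "and by the TAD model's expectation on real data.\n")

# densest 2 Mb region: peak content of the window around the most
# colocalized chromosome's median gene
hits <- coloc[coloc$within_window, ]
ch <- names(sort(table(hits$chrom), decreasing = TRUE))[1]
center <- median(hits$anchor[hits$chrom == ch])
region <- data.frame(chrom = ch, start = max(0, center - 1e6),
                     end = center + 1e6)
cat(sprintf("Example 2 Mb region %s:%d-%d contains %d persistent sites\n",
            ch, region$start, region$end,
            count_region_peaks(region, peak_bed)))
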