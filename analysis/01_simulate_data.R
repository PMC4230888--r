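#!/usr/bin/env Rscript
# Generate the synthetic study datasets with planted ground truth and write
# them in the standard formats (FASTA, tabular similarity, GFF3, newick,
# JSON truth bundles) under results/data/. The generators are pure
# functions of their seed, so downstream drivers regenerate the same
# objects in memory from the seeds recorded here.

suppressPackageStartupMessages(library(halopan))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
SEED <- 20260901L

## Pangenome: 12 genomes in 3 genera, 25 core + 60 accessory families plus
## 3 private families per genus, with sub-threshold noise edges.
pg <- gen_pangenome(n_genomes = 12L, n_genera = 3L, n_core = 25L,
                    n_accessory = 60L, n_noise_edges = 100L, seed = SEED)
write_fasta(pg$proteins, file.path(out, "proteomes.faa"))
write_similarity_table(pg$edges, file.path(out, "allvall.tsv"))
write.table(data.frame(species_id = pg$species,
                       genus = pg$genus_of[pg$species]),
            file.path(out, "species.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write_truth_bundle(pg$truth, file.path(out, "pangenome_truth.json"))
cat(sprintf("pangenome: %d proteins, %d planted families, %d edges\n",
            nrow(pg$proteins), length(pg$truth$families$families),
            nrow(pg$edges)))

## Genome with one planted low-G+C island (62% background, 45% island).
gg <- gen_genome(contig_lengths = c(contig_1 = 50000L), background_gc = 0.62,
                 segments = data.frame(contig = "contig_1", start = 20000L,
                                       length = 5000L, gc = 0.45),
                 n_fraction = 0.002, seed = SEED + 1L)
write_fasta(gg$contigs, file.path(out, "genome.fna"))
write_truth_bundle(gg$truth, file.path(out, "genome_truth.json"))
cat("genome: 50 kb with a 5 kb planted 45% G+C island\n")

## Bimodal proteome for the isoelectric-point analysis.
pr <- gen_proteome(n = 600L, acidic_fraction = 0.8, seed = SEED + 2L)
write_fasta(pr$proteins, file.path(out, "pi_proteome.faa"))
write_truth_bundle(pr$truth, file.path(out, "pi_proteome_truth.json"))
cat("proteome: 600 proteins, 80% acidic mode\n")

## Gene-tree corpus across the four transfer scenarios.
dir.create(file.path(out, "trees"), showWarnings = FALSE)
truth_all <- NULL
for (sc in c("basal_transfer", "multiple_transfer", "no_transfer",
             "scattered")) {
  g <- gen_gene_trees(sc, n_trees = 50L, seed = SEED + 3L)
  writeLines(vapply(g$trees, ape::write.tree, character(1)),
             file.path(out, "trees", paste0(sc, ".nwk")))
  g$truth$file <- paste0(sc, ".nwk")
  truth_all <- rbind(truth_all, g$truth)
}
write.table(truth_all, file.path(out, "trees", "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("gene trees: %d across 4 scenarios\n", nrow(truth_all)))

## Conserved-neighborhood missed-gene case (one hidden gene).
mg <- gen_missed_gene_case(n_species = 6L, deleted_species = 2L,
                           seed = SEED + 4L)
for (sp in names(mg$genomes)) {
  write_fasta(mg$genomes[[sp]], file.path(out, paste0(sp, ".fna")))
  write_features(mg$features[[sp]], file.path(out, paste0(sp, ".gff3")))
}
write_family_set(mg$families, file.path(out, "missed_gene_families.txt"))
cat("missed-gene case: 6 species, target hidden in species 2\n")
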