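#!/usr/bin/env Rscript
# Simulate the study cohort: a dated genealogy of 60 modern Y chromosomes
# under a piecewise-constant demography, infinite-sites SNPs over a 9.4 Mb
# callable region, Brownian tip geography, 8-locus STR haplotypes, and a
# contaminated call set carrying the four QC artifact classes.
#
# Outputs (results/): truth tree (Newick, years), raw VCF + tiled BED
# mask, tip locations and STRs (TSV), artifact truth (JSON).

library(ychron)
seed <- 20260926L
dir.create("results", showWarnings = FALSE)

L <- 9.4e6
# two-epoch demography (recent expansion over a small ancestral pool);
# the genealogy's time scale is then calibrated to a study-like TMRCA
dem <- demography_model(c(12000, 1200), times = c(0, 15000))
tree <- simulate_genealogy(60, dem, seed = seed)
tree$edge.length <- tree$edge.length * 20300 / max(node_ages(tree))
message(sprintf("genealogy: 60 tips, TMRCA %.0f yr BP",
                max(node_ages(tree))))

sim <- drop_mutations(tree, mu = 7e-10, L = L, seed = seed + 1)
sim$matrix$mask <- tiled_mask(L)
sim <- respace_singleton_runs(sim, seed = seed + 2)
message(sprintf("clean call set: %d SNPs", nrow(sim$matrix$geno)))

inj <- inject_qc_artifacts(sim$matrix, tree,
                           spec = list(singleton_clusters = 6,
                                       replicate_discordances = 2,
                                       recurrent_sites = 4,
                                       missing_blocks = 3),
                           seed = seed + 3)
message(sprintf("contaminated call set: %d SNPs x %d samples",
                nrow(inj$matrix$geno), ncol(inj$matrix$geno)))

loc <- simulate_brownian_locations(tree, root_location = c(35, 45),
                                   sigma = 8, seed = seed + 4)
strs <- simulate_str_haplotypes(tree, str_rate = 0.002, seed = seed + 5)

write_tree_newick(tree, "results/truth_tree.nwk")
write_genotype_vcf(inj$matrix, "results/raw_calls.vcf")
write_bed(inj$matrix$mask, "results/callable_mask.bed")
n <- length(tree$tip.label)
pops <- paste0("POP", 1 + as.integer(cut(loc$lon[1:n], 5)))
write_tsv(data.frame(sample = tree$tip.label,
                     lat = round(loc$lat[1:n], 5),
                     lon = round(loc$lon[1:n], 5),
                     population = pops),
          "results/tip_locations.tsv")
write_tsv(cbind(data.frame(sample = rownames(strs$repeats)),
                as.data.frame(strs$repeats)),
          "results/str_haplotypes.tsv")
jsonlite::write_json(
  list(replicate_groups = lapply(inj$truth$replicate_discordances,
                                 `[[`, "group"),
       singleton_clusters = inj$truth$singleton_clusters,
       recurrent_sites = inj$truth$recurrent_sites,
       missing_blocks = inj$truth$missing_blocks,
       root_location = c(35, 45), mu = 7e-10, L = L, seed = seed),
  "results/simulation_truth.json", auto_unbox = TRUE, digits = NA)
message("wrote results/{truth_tree.nwk, raw_calls.vcf, callable_mask.bed,")
message("  tip_locations.tsv, str_haplotypes.tsv, simulation_truth.json}")
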