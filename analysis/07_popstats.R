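#!/usr/bin/env Rscript
# Population statistics: per-population 8-locus STR gene diversity,
# branch frequency table at the first split, and interpolated spatial
# surfaces (ordinary kriging) of branch frequency and diversity.

library(ychron)

tips <- read_tsv("results/tip_locations.tsv")
strs <- read_tsv("results/str_haplotypes.tsv")
tree <- read_tree_newick("results/haplotree.nwk")
names_tab <- read_tsv("results/branch_names.tsv")

# sample -> deepest named branch below the root's major/minor split
level <- names_tab$name[nchar(names_tab$name) == 3 &
                          names_tab$node > length(tree$tip.label)]
tu <- tips_under(tree)
asng <- do.call(rbind, lapply(level, function(nm) {
  node <- names_tab$node[names_tab$name == nm][1]
  data.frame(sample = tree$tip.label[tu[[node]]], branch = nm)
}))
freq <- branch_frequency_table(asng, tips[, c("sample", "population")])
write_tsv(freq, "results/branch_frequencies.tsv")
message("branch frequencies at the first split:")
print(freq)

div <- vapply(split(strs, tips$population[match(strs$sample, tips$sample)]),
              function(d) if (nrow(d) >= 2)
                str_gene_diversity(as.matrix(d[, YSTR_LOCI])) else NA_real_,
              numeric(1))
message("per-population STR gene diversity:")
print(round(div, 3))

centers <- aggregate(cbind(lat, lon) ~ population, tips, mean)
pts <- data.frame(lat = centers$lat, lon = centers$lon,
                  value = div[centers$population])
pts <- pts[is.finite(pts$value), ]
if (nrow(pts) >= 3) {
  surf <- interpolate_surface(pts, list(n = 60),
                              method = "ordinary_kriging")
  write_tsv(data.frame(lon = rep(surf$lon, length(surf$lat)),
                       lat = rep(surf$lat, each = length(surf$lon)),
                       diversity = as.vector(surf$values)),
            "results/diversity_surface.tsv")
  message("wrote results/diversity_surface.tsv (ordinary kriging)")
}
write_tsv(data.frame(population = names(div),
                     gene_diversity = round(div, 4)),
          "results/str_diversity.tsv")
message("wrote results/{branch_frequencies.tsv, str_diversity.tsv}")
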