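# Small in-code cohort builders shared across the suite.

make_cohort <- function(variant_id,
                        curated_tier = "vus",
                        evidence = "",
                        am_score = NA_real_,
                        am_category = NA_character_,
                        gene = NA_character_,
                        revel_score = NA_real_) {
  tibble::tibble(
    variant_id = variant_id,
    gene = gene,
    curated_tier = curated_tier,
    evidence = evidence,
    am_score = am_score,
    am_category = am_category,
    revel_score = revel_score)
}

# A tiny mixed cohort exercising all tiers and both AM input routes.
tiny_cohort <- function() {
  make_cohort(
    variant_id = paste0("v", 1:6),
    curated_tier = c("vus", "vus", "vus", "pathogenic", "benign",
                     "likely_pathogenic"),
    evidence = c("", "PM2;PP1", "PM2;PP3", "PVS1;PS3;PM2", "BA1;BS1",
                 "PS4;PM2;PP1"),
    am_score = c(0.20, 0.90, 0.90, 0.95, 0.10, 0.45))
}
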