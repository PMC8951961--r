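# Regenerates inst/extdata/imd_evaluation.csv, the bundled reference
# evaluation of 48 inherited metabolic disorders.
#
# Each row carries both the published seven sub-scores plus total
# (printed_*) and evidence-level fields derived from them through the
# inverse of the scoring maps, so tests can separate "the engine maps
# evidence to points correctly" from "the fixture was transcribed
# correctly". The per-disorder birth-prevalence estimates behind the
# frequency sub-scores are not distributed; the prevalence column holds
# SYNTHETIC band-representative values (1/40000, 1/75000, 1/120000,
# 1/200000, absent) with provenance "unknown".
#
# Run from the package root: Rscript data-raw/make_fixture.R

rows <- "
cud|DFAM|Carnitine uptake defect/carnitine transport defect (CUD)|12.5|1.5|2|2|2|1|1.5|2.5
scid|other|Severe combined immunodeficiency (SCID)|12|2|2|2|2|0.5|1.5|2
ga1|DOAM|Glutaric aciduria type 1 (GA1)|11.5|2|2|1.5|2|1|1|2
hcu|DAAM|Homocystinuria (HCU)|11.5|1.5|2|1|2|1|1.5|2.5
pku|DAAM|Phenylketonuria (PKU)|11.5|0.5|2|2|2|1|1.5|2.5
tyr1|DAAM|Tyrosinemia, type 1 (TYR 1)|11.5|1.5|2|1.5|2|0.5|1.5|2.5
galt|other|Classic galactosaemia (GALT)|11|2|1|2|2|1|1|2
hmg|DOAM|3-Hydroxy-3-methyglutaric aciduria (HMG)|11|1.5|2|1|2|1|1|2.5
pompe|LSD|Pompe disease|11|1.5|1|2|2|0.5|1.5|2.5
xald|other|X-linked adrenoleukodystrophy (X-ALD)|10.5|1.5|1|2|2|1|1|2
asa|DAAM|Argininosuccinic aciduria (ASA)|10.5|2|1|1.5|2|1|1.5|1.5
cpt1|DFAM|Carnitine palmitoyltransferase, type I deficiency (CPT I)|10.5|2|2|0|2|1|1|2.5
lchad|DFAM|Long-chain 3 hydroxyacyl-CoA dehydrogenase deficiency (LCHAD)|10.5|2|2|1|2|1|1|1.5
mma_cbl|DOAM|Methylmalonic acidaemia (cobalamin disorders, Cbl A, B)|10.5|2|2|0|2|1|1|2.5
mld|LSD|Metachromatic leukodystrophy (MLD)|10.5|2|2|1.5|1|0.5|1.5|2
mps1|LSD|Mucopolysaccharidosis, type I (MPS I)|10.5|1.5|2|1.5|2|0.5|1.5|1.5
prop|DOAM|Propionic acidaemia (PROP)|10.5|2|1|0.5|2|1|1.5|2.5
biot|other|Biotinidase deficiency (BIOT)|10.5|2|1|1.5|2|0.5|1|2.5
mcadd|DFAM|Medium-chain acyl-CoA dehydrogenase deficiency (MCADD)|10|1.5|1|2|2|1|1|1.5
mcc3|DOAM|3-Methylcrotonyl-CoA carboxylase deficiency (3MCC)|10|1.5|1|2|2|1|1|1.5
cit1|DAAM|Citrullinemia, type I (CIT)|10|1.5|1|0.5|2|1|1.5|2.5
mcd|DOAM|Holocarboxylase synthetase deficiency (MCD)|10|2|1|0.5|2|1|1|2.5
krabbe|LSD|Krabbe disease|10|1.5|2|1.5|2|0.5|1|1.5
arg|DAAM|Argininaemia (ARG)|9.5|1.5|2|0|2|0.5|1|2.5
cact|DFAM|Carnitine acylcarnitine translocase deficiency (CACT)|9.5|2|1|0|2|1|1|2.5
vlcad|DFAM|Very long-chain acyl-CoA dehydrogenase deficiency (VLCAD)|9.5|1.5|1|2|2|1|1|1
msud|DAAM|Maple syrup urine disease (MSUD)|9|1.5|0|1|2|1|1|2.5
mut|DOAM|Methylmalonic acidaemia (methylmalonyl-CoA mutase) (MUT)|9|1.5|1|0.5|2|1|1|2
cpt2|DFAM|Carnitine palmitoyltransferase, type II deficiency (CPT II)|9|1.5|1|0|2|1|1|2.5
cln2|LSD|Batten disease (CLN2)|9|2|2|0|1|1|1.5|1.5
npab|LSD|Niemann Pick A/B (ASM deficiency)|9|2|2|0.5|2|1|1|0.5
iva|DOAM|Isovaleric acidaemia (IVA)|8.5|1.5|0|1|2|1|1|2
tfp|DFAM|Trifunctional protein deficiency (TFP)|8.5|1.5|1|0|2|1|1|2
gaucher|LSD|Gaucher disease|8.5|1.5|1|1.5|2|0.5|1.5|0.5
lald|LSD|Lysosomal acid lipase deficiency (LAL-D/Wolman/CESD)|8.5|1.5|1|0.5|2|1|1.5|1
madd|DFAM|Multiple acyl-CoA dehydrogenase deficiency (MADD)|8|1.5|0|0.5|2|1|1|2
mps6|LSD|MPS VI (Maroteaux-Lamy syndrome)|8|1.5|2|0|1|0.5|1.5|1.5
alpha_mann|LSD|Alpha-mannosidosis|7.5|1.5|1|0|1|1|1.5|1.5
fabry|LSD|Fabry disease|7.5|0|1|1.5|2|0.5|1.5|1
mps2|LSD|MPS II (Hunter syndrome)|7|0|2|0.5|1|0.5|1.5|1.5
mps3|LSD|MPS III (Sanfilippo syndrome)|6.5|0|2|1.5|1|1|0.5|0.5
npc|LSD|Niemann-Pick type C disease|6.5|1.5|1|1|1|0|1.5|0.5
mps4|LSD|MPS IV (Morquio syndrome)|5.5|0|2|0|1|0.5|1.5|0.5
sandhoff|LSD|Sandhoff disease (GM2 gangliosidosis, type II)|5.5|1.5|2|1|0|0|1|0
farber|LSD|Farber disease|5|2|1|0|0|0|1|1
tay_sachs|LSD|Tay-Sachs disease (GM2 gangliosidosis, type I)|4.5|1.5|2|0|0|0|1|0
mps7|LSD|MPS VII (Sly syndrome)|3.5|1.5|0|0|0|0|1.5|0.5
mps9|LSD|MPS IX (hyaluronidase deficiency)|1|0|1|0|0|0|0|0
"

tab <- read.table(text = trimws(rows), sep = "|", quote = "",
                  stringsAsFactors = FALSE,
                  col.names = c("disorder_id", "disorder_class", "name",
                                "total", "severity", "onset", "frequency",
                                "screen_availability", "screen_performance",
                                "treat_availability", "treat_outcomes"))
stopifnot(nrow(tab) == 48,
          all(tab$total == tab$severity + tab$onset + tab$frequency +
                tab$screen_availability + tab$screen_performance +
                tab$treat_availability + tab$treat_outcomes))

fmt <- function(x) format(x, trim = TRUE, drop0trailing = TRUE)
map <- function(x, from, to) to[match(x, from)]

fixture <- data.frame(
  disorder_id = tab$disorder_id,
  name = tab$name,
  disorder_class = tab$disorder_class,
  severity_level = paste0("S", vapply(tab$severity, fmt, character(1))),
  onset_class = map(tab$onset, c(2, 1, 0),
                    c("all_forms_asymptomatic_first_weeks",
                      "some_forms_asymptomatic",
                      "symptomatic_at_birth_or_unknown")),
  prevalence = map(tab$frequency, c(2, 1.5, 1, 0.5, 0),
                   c("1/40000", "1/75000", "1/120000", "1/200000", "")),
  prevalence_provenance = "unknown",
  dbs_status = map(tab$screen_availability, c(2, 1, 0),
                   c("in_use_or_registered", "in_development", "none")),
  performance_class = map(tab$screen_performance, c(1, 0.5, 0),
                          c("low_fp_standalone", "second_tier_available",
                            "insufficient_or_none")),
  treatment_availability = map(tab$treat_availability, c(1.5, 1, 0.5, 0),
                               c("ema_approved", "phase3_or_intervention",
                                 "limited_intervention", "none")),
  outcomes_level = paste0("O", vapply(tab$treat_outcomes, fmt,
                                      character(1))),
  printed_severity = tab$severity,
  printed_onset = tab$onset,
  printed_frequency = tab$frequency,
  printed_screen_availability = tab$screen_availability,
  printed_screen_performance = tab$screen_performance,
  printed_treat_availability = tab$treat_availability,
  printed_treat_outcomes = tab$treat_outcomes,
  printed_total = tab$total,
  stringsAsFactors = FALSE)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.csv(fixture, "inst/extdata/imd_evaluation.csv", row.names = FALSE,
          quote = TRUE, fileEncoding = "UTF-8")
cat("wrote inst/extdata/imd_evaluation.csv:", nrow(fixture), "rows\n")
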