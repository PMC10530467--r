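# Dev-time generator for inst/extdata/fixture (plain-text fixture files).
# (regenerates the packaged fixture deterministically)
# Run from the repo root: Rscript data-raw/make_fixture.R
dir.create("inst/extdata/fixture", recursive = TRUE, showWarnings = FALSE)
out <- function(f) file.path("inst/extdata/fixture", f)
members <- c("I1", "II1", "II2", "II3", "III1", "III2")

V <- function(chrom, pos, ref, alt, gene, rsid, cdna, prot, cons,
              maf_g, maf_k, clinvar, novel, qual, het, hom = "") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             rsid = rsid, cdna = cdna, prot = prot, cons = cons,
             maf_g = maf_g, maf_k = maf_k, clinvar = clinvar,
             novel = novel, qual = qual, het = het, hom = hom,
             stringsAsFactors = FALSE)
}

tab <- rbind(
  # ---- the 22 low-frequency records (printed variant table) ----
  V("chr1", 159683091, "T", "C", "CRP", "rs1376711485", "c.182T > C",
    "p.Leu61Pro", "missense", "6.98295e-06", "6.98295e-06", "NR", FALSE,
    96.0, "I1;II2;II3;III1;III2"),
  V("chr1", 156869047, "C", "T", "PEAR1", "rs77795865", "c.1142C > T",
    "p.Ser381Phe", "missense", "0.0230726", "0.0230726", "NR", FALSE,
    92.0, "II2;II3"),
  V("chr1", 165721011, "C", "T", "TMCO1", "rs78363884", "c.486C > T",
    "p.Leu162=", "synonymous", "0.033832", "0.033832", "B", FALSE,
    88.0, "II2"),
  V("chr1", 43349011, "G", "A", "MPL", "rs544064034", "c.1242G > A",
    "p.Ser414=", "synonymous", "6.98227e-06", "6.98227e-06", "LB", FALSE,
    91.0, "II2;II3;III2"),
  V("chr1", 245419111, "C", "T", "KIF26B", "rs201717788", "c.507C > T",
    "p.Val169=", "synonymous", "0.00295131", "0.00295131", "NR", FALSE,
    87.0, "II1;III1;III2"),
  V("chr2", 24940133, "A", "G", "NCOA1", "rs150066931", "c.3995A > G",
    "p.Asn1332Ser", "missense", "0.0015095", "0.0015095", "NR", FALSE,
    94.0, "I1;II3"),
  V("chr2", 234637811, "G", "T", "UGT1A3", "rs146461519", "c.736G > T",
    "p.Val246Leu", "missense", "0.00043999", "0.00043999", "NR", FALSE,
    86.0, "II3"),
  V("chr8", 42039530, "C", "T", "PLAT", "rs2020921", "c.490C > T",
    "p.Arg164Trp", "missense", "0.012879", "0.012879", "NR", FALSE,
    97.0, "II3"),
  V("chr9", 5069022, "C", "G", "JAK2", "rs2230723", "c.1177C > G",
    "p.Leu393Val", "missense", "0.0134624", "0.0134624", "B", FALSE,
    95.0, "I1;II2;II3;III2"),
  V("chr11", 46750921, "C", "A", "F2", "rs199772906", "c.1542C > A",
    "p.Asn514Lys", "missense", "0.000244325", "0.000244325", "NR", FALSE,
    98.0, "I1;II2;II3;III2"),
  V("chr11", 18260033, "A", "C", "SAA2", "rs138605229", "c.222A > C",
    "p.Glu74Asp", "missense", "0.00552043", "0.00552043", "NR", FALSE,
    85.0, "II1;III1;III2"),
  V("chr12", 6128444, "G", "A", "VWF", "rs1800382", "c.4196G > A",
    "p.Arg1399His", "missense", "0.00895051", "0.00895051", "B;LB;LP;P",
    FALSE, 99.0, "II3"),
  V("chr14", 58765013, "C", "T", "ARID4A", "rs146509016", "c.8C > T",
    "p.Ala3Val", "missense", "4.18819e-05", "4.18819e-05", "NR", FALSE,
    90.0, "II1;III1;III2"),
  V("chr14", 58838511, "G", "C", "ARID4A", "rs1051029502", "c.2847G > C",
    "p.Met949Ile", "missense", "6.97876e-06", "6.97876e-06", "NR", FALSE,
    89.0, "I1;II3"),
  V("chr14", 94849022, "C", "T", "SERPINA1", "rs28931570", "c.187C > T",
    "p.Arg63Cys", "missense", "0.00151399", "0.00151399", "P;LP", FALSE,
    96.0, "II2;III1;III2"),
  V("chr15", 39886011, "T", "A", "THBS1", "-", "c.2703T > A",
    "p.Asp901Glu", "missense", NA, NA, "NR", TRUE, 93.0, "I1;II2;III2"),
  V("chr16", 69745145, "C", "T", "NQO1", "rs1131341", "c.415C > T",
    "p.Arg139Trp", "missense", "0.0255606", "0.0255606", "NR", FALSE,
    92.0, "I1;II2;II3;III2"),
  V("chr16", 81872011, "T", "C", "PLCG2", "rs138637229", "c.1146T > C",
    "p.Phe382=", "synonymous", "0.0071625", "0.0071625", "B;LB", FALSE,
    88.0, "II2"),
  V("chr19", 51561213, "C", "T", "KLK13", "rs34089525", "c.325C > T",
    "p.His109Tyr", "missense", "0.0217616", "0.0217616", "NR", FALSE,
    91.0, "II2;II3;III1"),
  V("chr19", 43255011, "G", "C", "PSG8", "-", "c.26G > C",
    "p.Cys9Ser", "missense", NA, NA, "NR", TRUE, 90.0,
    "I1;II2;II3;III1;III2"),
  V("chr20", 48184011, "C", "T", "PTGIS", "rs61322884", "c.531C > T",
    "p.Tyr177=", "synonymous", "0.0221135", "0.0221135", "NR", FALSE,
    87.0, "II3"),
  V("chr22", 21131011, "G", "A", "SERPIND1", "rs35646566", "c.423G > A",
    "p.Leu141=", "synonymous", "0.0173203", "0.0173203", "NR", FALSE,
    89.0, "I1;II3"),
  # ---- frequent / supplementary records (MAF >= 0.04 distractors) ----
  V("chr4", 155489011, "G", "A", "FGB", "rs4220", "c.1433G > A",
    "p.Arg478Lys", "missense", "0.22", "0.2", "NR", FALSE, 99.0,
    "I1;II2;II3;III2"),
  V("chr2", 113537011, "G", "T", "IL1A", "rs17561", "c.340G > T",
    "p.Ala114Ser", "missense", "0.3", "0.28", "NR", FALSE, 99.0,
    "I1;II2", hom = "III2"),
  V("chr1", 169519049, "A", "G", "F5", "rs6027", "c.5207T > C",
    "p.Met1736Val", "missense", "0.25", "0.24", "NR", FALSE, 98.0,
    "II2;II3;III2"),
  V("chr1", 201865011, "G", "A", "LMOD1", "rs2820312", "c.1234G > A",
    "p.Val412Ile", "missense", "0.3", "0.29", "NR", FALSE, 97.0,
    "I1;II1", hom = "II2;II3;III2"),
  V("chr3", 186444011, "C", "G", "KNG1", "rs3733402", "c.591C > G",
    "p.Ile197Met", "missense", "0.35", "0.33", "NR", FALSE, 96.0,
    "II1;III2"),
  V("chr19", 43255241, "G", "A", "PSG8", "rs900000001", "c.256G > A",
    "p.Gly86Ser", "missense", "0.15", "0.14", "NR", FALSE, 95.0,
    "I1;III2"),
  V("chr19", 43255248, "T", "G", "PSG8", "rs900000002", "c.263T > G",
    "p.Ile88Arg", "missense", "0.12", "0.11", "NR", FALSE, 94.0, "III2"),
  V("chr15", 39884911, "A", "G", "THBS1", "rs2292305", "c.1567A > G",
    "p.Thr523Ala", "missense", "0.21", "0.2", "NR", FALSE, 93.0,
    "II1;II2;III2"),
  V("chr15", 39885442, "A", "G", "THBS1", "rs2228262", "c.2099A > G",
    "p.Asn700Ser", "missense", "0.09", "0.085", "NR", FALSE, 92.0,
    "II1;II2;III2"),
  V("chr14", 94847011, "G", "A", "SERPINA1", "rs709932", "c.374G > A",
    "p.Arg125His", "missense", "0.24", "0.23", "NR", FALSE, 95.0,
    "II2;III1;III2"),
  V("chr14", 94844111, "A", "C", "SERPINA1", "rs1303", "c.1200A > C",
    "p.Glu400Asp", "missense", "0.19", "0.18", "NR", FALSE, 94.0,
    "II2;III1;III2"),
  V("chr12", 6125011, "G", "C", "VWF", "rs1800386", "c.4414G > C",
    "p.Asp1472His", "missense", "0.17", "0.16", "NR", FALSE, 96.0, "II3"),
  # ---- records exercising the other filter clauses ----
  V("chr4", 187192011, "G", "A", "F11", "rs900000003", "c.901G > A",
    "p.Ala301Thr", "missense", "0.002", "0.002", "NR", FALSE, 22.0,
    "II3"),                                    # fails quality
  V("chr2", 179400011, "C", "T", "TTN", "rs900000004", "c.10101C > T",
    "p.Pro3367Leu", "missense", "0.0005", "0.0005", "NR", FALSE, 99.0,
    "III2"),                                   # gene not on panel
  V("chr17", 45360011, "C", "T", "ITGB3", "rs900000005", "c.500C > T",
    "p.Thr167Ile", "missense", "0.003", "0.003", "NR", FALSE, 88.0,
    "II1;III1"),                               # het only in unaffected
  V("chr1", 169560011, "C", "T", "SELP", "rs900000006", "c.700C > T",
    "p.Arg234Cys", "missense", "0.01", "0.1", "NR", FALSE, 90.0,
    "II2;III2"),                               # fails 1000G < 0.04
  V("chr2", 128180011, "G", "A", "PROC", "rs900000007", "c.565G > A",
    "p.Val189Met", "missense", "0.002", "0.002", "NR", FALSE, 90.0,
    "II1", hom = "II3"),                       # hom-alt only in affected
  # ---- multiallelic site (both alleles frequent) ----
  V("chr6", 6318011, "A", "G", "F13A1", "rs5985", "c.103G > T",
    "p.Val34Leu", "missense", "0.25", "0.24", "NR", FALSE, 95.0, ""),
  V("chr6", 6318011, "A", "T", "F13A1", "rs5985", "c.103G > A",
    "p.Val34Met", "missense", "0.06", "0.055", "NR", FALSE, 95.0, "")
)

# ---------------- family.ped ----------------
ped <- c("FAM1\tI1\t0\t0\t1\t1",
         "FAM1\tII1\t0\t0\t2\t1",
         "FAM1\tII2\tI1\t0\t1\t2",
         "FAM1\tII3\tI1\t0\t1\t2",
         "FAM1\tIII1\tII2\tII1\t2\t1",
         "FAM1\tIII2\tII2\tII1\t1\t2")
writeLines(ped, out("family.ped"))

# ---------------- family.vcf ----------------
gt_of <- function(row, m, alt_index = 1) {
  het <- strsplit(row$het, ";")[[1]]
  hom <- strsplit(row$hom, ";")[[1]]
  if (m %in% hom) paste0(alt_index, "/", alt_index)
  else if (m %in% het) paste0("0/", alt_index)
  else "0/0"
}
hdr <- c("##fileformat=VCFv4.2",
         "##source=famvarnet-fixture",
         "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
         paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", members), collapse = "\t"))
body <- character(0)
i <- 1
while (i <= nrow(tab)) {
  r <- tab[i, ]
  if (r$chrom == "chr6" && r$pos == 6318011) {
    # single multiallelic line A -> G,T with handcrafted genotypes
    gts <- c(I1 = "1/2", II1 = "0/1", II2 = "0/2", II3 = "0/0",
             III1 = "0/0", III2 = "0/1")
    body <- c(body, paste(c(r$chrom, r$pos, r$rsid, "A", "G,T",
                            sprintf("%.1f", r$qual), "PASS", ".", "GT",
                            gts[members]), collapse = "\t"))
    i <- i + 2
    next
  }
  gts <- vapply(members, function(m) gt_of(r, m), "")
  id <- if (r$rsid == "-") "." else r$rsid
  body <- c(body, paste(c(r$chrom, r$pos, id, r$ref, r$alt,
                          sprintf("%.1f", r$qual), "PASS", ".", "GT",
                          gts), collapse = "\t"))
  i <- i + 1
}
writeLines(c(hdr, body), out("family.vcf"))

# ---------------- variants.tsv (side-car annotation) ----------------
ann <- data.frame(chrom = tab$chrom, pos = tab$pos, ref = tab$ref,
                  alt = tab$alt, gene = tab$gene,
                  rsid = ifelse(tab$rsid == "-", NA, tab$rsid),
                  cdna_change = tab$cdna, protein_change = tab$prot,
                  consequence = tab$cons, maf_gnomad3 = tab$maf_g,
                  maf_1000g = tab$maf_k, clinvar = tab$clinvar,
                  novel = tab$novel, stringsAsFactors = FALSE)
write.table(ann, out("variants.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE, na = ".")

# ---------------- panel.txt (192 candidate genes) ----------------
panel <- c(
  # genes appearing in the fixture data (TTN deliberately absent)
  "ARID4A", "CRP", "F2", "JAK2", "KLK13", "NCOA1", "NQO1", "PEAR1",
  "PLAT", "PSG8", "SAA2", "SERPINA1", "THBS1", "UGT1A3", "VWF",
  "KIF26B", "MPL", "PLCG2", "PTGIS", "SERPIND1", "TMCO1",
  "FGB", "IL1A", "F5", "LMOD1", "KNG1", "F11", "SELP", "PROC",
  "ITGB3", "F13A1", "SAA1", "HP", "ORM1", "NOS3", "EDN1",
  # coagulation / fibrinolysis
  "F3", "F7", "F8", "F9", "F10", "F12", "F13B", "FGA", "FGG", "PROS1",
  "SERPINC1", "SERPINE1", "SERPINF2", "SERPINB2", "PLG", "PLAU",
  "PLAUR", "THBD", "PROCR", "TFPI", "HRG", "KLKB1", "ADAMTS13",
  "CPB2", "HABP2", "GGCX", "VKORC1", "PROZ", "SERPINA10", "SERPING1",
  "A2M", "PZP", "AMBP", "MAST2", "STX2", "STXBP5", "VAMP8", "APOH",
  "KLK8", "KLK11", "SLC4A1", "SLC44A2", "TSPAN15", "F11R",
  # platelet biology
  "GP1BA", "GP1BB", "GP5", "GP6", "GP9", "ITGA2", "ITGA2B", "ITGB1",
  "CD36", "P2RY12", "P2RY1", "TBXA2R", "TBXAS1", "PTGS1", "PTGS2",
  "PF4", "PPBP", "THPO", "GATA1", "NFE2", "RUNX1", "MYB", "TUBB1",
  "MYH9", "DIAPH1", "RAP1B", "PIK3CG", "ARHGEF3", "AKT1", "AKT2",
  "MAPK1", "MAPK3", "SRC", "FYN", "LYN", "SYK", "FCGR2A", "FCER1G",
  "PLA2G4A", "PLCB2", "PRKCA", "PRKCB", "ITPR1", "ORAI1", "STIM1",
  "TRPC6", "CALM1", "MYL9", "TLN1", "VCL", "ACTN1", "FLNA", "WAS",
  "ANXA5", "ANXA2",
  # inflammation / immunity
  "IL1B", "IL1RN", "IL6", "IL6R", "IL10", "IL18", "TNF", "TNFRSF1A",
  "TNFRSF1B", "CXCL8", "CCL2", "ICAM1", "VCAM1", "SELE", "SELL",
  "PECAM1", "CD40", "CD40LG", "C3", "C5", "CFH", "CFB", "MBL2",
  "S100A8", "S100A9", "MIF", "TLR2", "TLR4", "NLRP3", "STAB2",
  # vascular tone / endothelium
  "EDNRA", "EDNRB", "ACE", "AGT", "AGTR1", "REN", "KLK1", "BDKRB1",
  "BDKRB2", "NOS2", "HMOX1",
  # lipids / metabolism / redox
  "APOE", "APOB", "APOA1", "LPL", "LIPC", "CETP", "PCSK9", "LDLR",
  "PON1", "MTHFR", "MTR", "CBS", "NQO2", "CYP2C9", "ABO", "FUT2")
panel <- unique(panel)
stopifnot(length(panel) == 192)
writeLines(c("# candidate gene panel (n = 192)", panel), out("panel.txt"))

# ---------------- regulatory.tsv (QTL / regulatory features) ----------
R <- function(rsid, gene, prot, region, splicing, eqtl, sqtl)
  data.frame(rsid = rsid, gene = gene, protein_change = prot,
             region_features = region, splicing = splicing,
             eqtl = eqtl, sqtl = sqtl, stringsAsFactors = FALSE)
reg <- rbind(
  R("rs146509016", "ARID4A", "p.Ala3Val", "missense;splice_region",
    "ESE_disruption", "no data", "no data"),
  R("rs1051029502", "ARID4A", "p.Met949Ile", "missense",
    "ESE_disruption", "no data", "no data"),
  R("rs199772906", "F2", "p.Asn514Lys", "missense", "ESE_disruption",
    "no data", "no data"),
  R("rs2230723", "JAK2", "p.Leu393Val", "missense",
    "new_ESS;ESE_disruption;new_donor", "no data", "no data"),
  R("rs34089525", "KLK13", "p.His109Tyr", "missense", "new_ESS",
    "IGLON5", "not found"),
  R("rs544064034", "MPL", "p.Ser414=", "synonymous;enhancer",
    "none", "no data", "no data"),
  R("rs150066931", "NCOA1", "p.Asn1332Ser", "missense",
    "ESE_disruption", "no data", "no data"),
  R("rs1131341", "NQO1", "p.Arg139Trp",
    "missense;splice_region;open_chromatin", "donor_disruption",
    "NOB1;COG4;PDXDC2P", "NQO1;NOB1;NPIPB14P"),
  R("rs77795865", "PEAR1", "p.Ser381Phe", "missense", "none",
    "LRRC71", "not found"),
  R("rs2020921", "PLAT", "p.Arg164Trp", "missense",
    "new_ESE;new_donor", "PLAT;POLB;AP3M2", "SLC20A2;POLB"),
  R("rs138605229", "SAA2", "p.Glu74Asp", "missense", "ESE_disruption",
    "ns", "not found"),
  R("rs146461519", "UGT1A3", "p.Val246Leu", "missense", "new_donor",
    "no data", "no data"),
  R("rs138637229", "PLCG2", "p.Phe382=", "synonymous;CTCF_site",
    "new_ESS", "ns", "not found"),
  R("rs61322884", "PTGIS", "p.Tyr177=", "synonymous",
    "ESE_disruption", "SLC9A8", "not found"),
  R("rs35646566", "SERPIND1", "p.Leu141=", "synonymous;enhancer",
    "ESE_disruption", "AC000089.3", "not found"),
  R("rs78363884", "TMCO1", "p.Leu162=", "synonymous", "new_ESS",
    "RP11-466F5.10", "not found"))
write.table(reg, out("regulatory.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE, na = ".")

# ---------------- prediction scores (16 missense x 15 tools) ----------
# Categories are the ground truth (the printed numeric panel is not
# machine-readable); raw scores are synthetic values consistent with the
# per-variant damaging-vote counts and with the REVEL ranking statements.
tools <- c("ClinPred", "DANNCoding", "MetaSVM", "REVEL", "VEST4",
           "FATHMM-XF", "MetaLR", "PhD-SNPg", "LRT", "MutationAssessor",
           "MutationTaster", "PROVEAN", "PolyPhen-2", "SIFT", "CADD")
pref <- c("SIFT", "PhD-SNPg", "FATHMM-XF", "LRT", "MutationTaster",
          "PROVEAN", "PolyPhen-2", "MutationAssessor", "ClinPred",
          "VEST4", "MetaSVM", "MetaLR", "DANNCoding", "CADD")
mis <- tab[tab$cons == "missense" & !is.na(tab$maf_g) |
             (tab$cons == "missense" & tab$novel), ]
# the 16 low-frequency missense records in fixed (REVEL-rank) order:
key_of <- function(g, p) {
  r <- tab[tab$gene == g & tab$prot == p, ][1, ]
  paste(r$chrom, r$pos, r$ref, r$alt, sep = ":")
}
spec16 <- list(  # gene, protein, REVEL, damaging votes
  list("CRP", "p.Leu61Pro", 0.95, 12),
  list("F2", "p.Asn514Lys", 0.91, 11),
  list("SERPINA1", "p.Arg63Cys", 0.88, 11),
  list("VWF", "p.Arg1399His", 0.84, 10),
  list("THBS1", "p.Asp901Glu", 0.80, 9),
  list("PLAT", "p.Arg164Trp", 0.72, 7),
  list("ARID4A", "p.Ala3Val", 0.65, 6),
  list("PEAR1", "p.Ser381Phe", 0.60, 6),
  list("UGT1A3", "p.Val246Leu", 0.49, 2),
  list("JAK2", "p.Leu393Val", 0.47, 2),
  list("ARID4A", "p.Met949Ile", 0.44, 5),
  list("SAA2", "p.Glu74Asp", 0.40, 2),
  list("PSG8", "p.Cys9Ser", 0.35, 2),
  list("NCOA1", "p.Asn1332Ser", 0.30, 4),
  list("KLK13", "p.His109Tyr", 0.26, 5),
  list("NQO1", "p.Arg139Trp", 0.22, 5))
scores <- matrix(NA_real_, 16, length(tools),
                 dimnames = list(NULL, tools))
keys <- character(16)
for (i in seq_along(spec16)) {
  s <- spec16[[i]]
  keys[i] <- key_of(s[[1]], s[[2]])
  revel <- s[[3]]; votes <- s[[4]]
  dmg <- character(0)
  n_fill <- votes
  if (revel >= 0.5) { dmg <- "REVEL"; n_fill <- votes - 1 }
  dmg <- c(dmg, pref[seq_len(n_fill)])
  for (j in seq_along(tools)) {
    tl <- tools[j]
    if (tl == "REVEL") { scores[i, j] <- revel; next }
    if (tl %in% dmg) {
      scores[i, j] <- 0.55 + 0.04 * ((i + j) %% 10)
    } else if ((i + j) %% 3 == 0) {
      scores[i, j] <- 0.28 + 0.02 * ((i + j) %% 10)  # moderate
    } else {
      scores[i, j] <- 0.05 + 0.015 * ((i + j) %% 10) # neutral
    }
  }
  stopifnot(sum(scores[i, ] >= 0.5) == votes)
}
sc <- data.frame(key = keys, scores, check.names = FALSE)
write.table(sc, out("scores.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cut <- data.frame(tool = tools, damaging_min = 0.5, neutral_max = 0.25)
write.table(cut, out("cutoffs.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

# ---------------- edge_db.tsv (mini interaction database) -------------
E <- function(a, b, ch, s) data.frame(protein_a = a, protein_b = b,
                                      channel = ch, score = s,
                                      stringsAsFactors = FALSE)
edges <- rbind(
  E("F2", "CRP", "experimental", 0.85), E("F2", "CRP", "database", 0.80),
  E("F2", "CRP", "coexpression", 0.60),
  E("F2", "FGB", "database", 0.92), E("F2", "FGB", "experimental", 0.70),
  E("F2", "VWF", "experimental", 0.90), E("F2", "VWF", "database", 0.85),
  E("F2", "VWF", "cooccurrence", 0.30),
  E("PLAT", "VWF", "experimental", 0.88), E("PLAT", "VWF", "database", 0.80),
  E("FGB", "THBS1", "experimental", 0.75),
  E("FGB", "SERPINA1", "database", 0.72),
  E("FGB", "VWF", "experimental", 0.60), E("FGB", "VWF", "coexpression", 0.45),
  E("CRP", "FGB", "experimental", 0.78), E("CRP", "FGB", "coexpression", 0.55),
  E("F2", "SERPINA1", "experimental", 0.82),
  E("CRP", "VWF", "database", 0.74),
  E("CRP", "IL1A", "experimental", 0.55), E("CRP", "IL1A", "coexpression", 0.50),
  E("CRP", "SERPINA1", "coexpression", 0.45),
  E("THBS1", "VWF", "experimental", 0.50),
  E("F2", "THBS1", "database", 0.42),
  E("CRP", "THBS1", "coexpression", 0.30),
  E("FGB", "IL1A", "experimental", 0.35),
  E("F2", "PLAT", "experimental", 0.65),
  E("CRP", "SAA1", "experimental", 0.60),
  E("FGB", "FGA", "neighborhood", 0.90),
  E("FGB", "FGA", "fusion", 0.30))
write.table(edges, out("edge_db.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

# ---------------- terms.gmt ----------------
gmt <- c(
  paste(c("GO:0006953", "GO-BP:acute-phase response",
          "CRP", "F2", "SERPINA1", "IL1A", "SAA1", "SAA2", "HP",
          "ORM1"), collapse = "\t"),
  paste(c("KW-0011", "keyword:Acute phase",
          "CRP", "F2", "SERPINA1", "IL1A", "SAA1", "SAA2"),
        collapse = "\t"),
  paste(c("GOCC:0005577", "GO-CC:fibrinogen complex",
          "FGB", "F2", "CRP", "THBS1", "VWF", "PLAT"), collapse = "\t"),
  paste(c("GO:0008015", "GO-BP:blood circulation",
          "F5", "F2", "VWF", "NOS3", "EDN1", "ACE", "AGT", "REN"),
        collapse = "\t"))
writeLines(gmt, out("terms.gmt"))

# ---------------- config.json ----------------
cfg <- list(
  maf_max = 0.04, qual_min = 30, votes_min = 4, affected_min = 2,
  prior = 0.041,
  tier_bounds = list(low = 0.15, medium = 0.4, high = 0.7, highest = 0.9),
  manual_includes = c("FGB", "IL1A"),
  network_eligible = c("CRP", "F2", "SERPINA1", "THBS1", "VWF", "PLAT"),
  extra_includes = list(II2 = list("FGB"), II3 = list("FGB"),
                        III2 = list("FGB", "IL1A")))
jsonlite::write_json(cfg, out("config.json"), auto_unbox = TRUE,
                     pretty = TRUE)
cat("fixture written\n")
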