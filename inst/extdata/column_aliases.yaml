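# Column-name alias library for heterogeneous GWAS summary-statistics files.
# Each canonical field maps to an ordered list of accepted header names
# (matched case-insensitively, first hit wins). Users can edit or extend and
# pass the file to parse_sumstats(column_map = read_column_map(path)).
rsid: [rsid, snp, snpid, markername, rs, variant_id, id, snp_id]
chr: [chr, chromosome, chrom, hg19chrc, "#chrom"]
pos: [pos, position, bp, base_pair_location, pos_b37, bp_hg19]
a1: [a1, effect_allele, allele1, ea, alt, testedallele]
a0: [a0, other_allele, allele2, allele0, nea, ref, a2, noneffect_allele]
beta: [beta, b, effect, est, beta1, effect_size]
or: [or, odds_ratio, oddsratio]
z: [z, zscore, z_score, zstat]
se: [se, stderr, standard_error, se_beta, sebeta]
freq: [freq, af, eaf, maf, effect_allele_frequency, frq, freq1, a1freq]
# "n" quoted: bare n is a YAML 1.1 boolean
"n": ["n", n_eff, neff, sample_size, n_total, totaln]
n_cases: [n_cases, ncase, ncases, n_cas, cases]
n_controls: [n_controls, ncontrol, ncontrols, n_con, controls]
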