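# End-to-end demo: simulate an edited read set on the demo amplicon, align,
# classify and quantify. Paths are relative to this directory; run from here
# or use demo_run_config(), which resolves them for you.
mode: simulate
amplicon_fasta: demo_amplicon.fasta
amplicon_annotation: demo_amplicons.tsv
amplicon_name: demo_site
n_reads: 1000
indel_freq: 0.25
tag_freq: 0.05
sub_position: 5
sub_from: A
sub_to: G
sub_freq: 0.20
seq_error_rate: 0.001
read_len: 50
call_mode: all
seed: 42
out_dir: crisprquant_demo_out
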