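# Exclusion code lists for cohort construction. The conditions are fixed by
# the method (ADRD, psychosis, prior MCI, bipolar disorder, dementia /
# antipsychotic medications); the codes are site configuration. These are the
# synthetic codes emitted by the package's corpus generator - replace with
# local ICD / pharmacy codes for real data.
adrd:
- DX_ADRD
- DX_AD
psychosis:
- DX_PSYCHOSIS
mci:
- DX_MCI
bipolar:
- DX_BIPOLAR
medications:
- RX_DONEPEZIL
- RX_ANTIPSYCHOTIC
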