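# Context patterns used to enrich training corpora with narratives likely
# to contain person names. One PCRE per line; '#' starts a comment.
# Patterns target name *contexts* (salutations, labels, sign-offs) and
# initial-like uppercase pairs, not names themselves.
(?i)\b(?:dr|doctor|mr|mrs|ms|miss|prof|professor|sister|nurse)\.?\s+\p{Lu}
(?i)\b(?:name|patient|reporter|physician|consultant|signed|contact)\s*:
\b\p{Lu}\.?\s?\p{Lu}\.?(?=[\s,.;:)]|$)
(?i)\b(?:kind regards|best regards|yours sincerely|many thanks),?\s+\S
\b(?:M\.?D\.?|Ph\.?D\.?|RN|MBBS|FRCP)\b
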