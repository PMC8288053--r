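# section-header regular expressions. Matching is case-SENSITIVE so that
# ordinary prose ("these results show") is not mistaken for a header;
# patterns cover Title-case and ALL-CAPS header forms. "keep" headers open
# spans retained by select_sections(); "boundary" headers close them.
keep:
  results: "\\b(?:RESULTS?(?: AND DISCUSSION)?|Results?(?: [Aa]nd [Dd]iscussion)?)\\b"
  discussion: "\\b(?:DISCUSSION|Discussion|Concluding [Rr]emarks|CONCLUDING REMARKS)\\b"
boundary:
  abstract: "\\b(?:ABSTRACT|Abstract)\\b"
  introduction: "\\b(?:INTRODUCTION|Introduction|BACKGROUND|Background)\\b"
  methods: "\\b(?:MATERIALS? AND METHODS|Materials? [Aa]nd [Mm]ethods|METHODS|Methods|EXPERIMENTAL PROCEDURES|Experimental [Pp]rocedures)\\b"
  conclusions: "\\b(?:CONCLUSIONS?|Conclusions?)\\b"
  acknowledgements: "\\b(?:ACKNOWLEDG|Acknowledg)\\w+"
  references: "\\b(?:REFERENCES|References|BIBLIOGRAPHY|Bibliography|LITERATURE CITED|Literature [Cc]ited)\\b"
  supplementary: "\\b(?:SUPPLEMENTARY INFORMATION|Supplementary [Ii]nformation|SUPPORTING INFORMATION|Supporting [Ii]nformation)\\b"
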