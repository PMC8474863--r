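{
  "amplicons": [
    {
      "name": "upstream_box",
      "group": "rhesus_box",
      "source_class": "upstream_box",
      "genomic_start": 25592579,
      "strand": "+",
      "primer_spans": {
        "forward": [1, 20],
        "reverse": [81, 105]
      },
      "diagnostic_sites": [
        {
          "amplicon_offset": 50,
          "genomic_pos": 25592628,
          "expected_base_by_source": {
            "upstream_box": "G",
            "downstream_box": "A"
          }
        }
      ]
    },
    {
      "name": "downstream_box",
      "group": "rhesus_box",
      "source_class": "downstream_box",
      "genomic_start": 25662906,
      "strand": "+",
      "primer_spans": {
        "forward": [1, 20],
        "reverse": [81, 105]
      },
      "diagnostic_sites": [
        {
          "amplicon_offset": 50,
          "genomic_pos": 25662955,
          "expected_base_by_source": {
            "upstream_box": "G",
            "downstream_box": "A"
          }
        }
      ]
    },
    {
      "name": "RHD_ex9",
      "group": "exon9",
      "source_class": "RHD_wt",
      "genomic_start": 25648397,
      "strand": "+",
      "primer_spans": {
        "forward": [1, 22],
        "reverse": [120, 148]
      },
      "diagnostic_sites": [
        {
          "amplicon_offset": 23,
          "genomic_pos": 25648419,
          "expected_base_by_source": {
            "RHD_wt": "A",
            "RHD_var": "A",
            "RHCE": "T"
          }
        },
        {
          "amplicon_offset": 57,
          "genomic_pos": 25648453,
          "expected_base_by_source": {
            "RHD_wt": "G",
            "RHD_var": "A",
            "RHCE": "C"
          }
        },
        {
          "amplicon_offset": 119,
          "genomic_pos": 25648515,
          "expected_base_by_source": {
            "RHD_wt": "A",
            "RHD_var": "A",
            "RHCE": "G"
          }
        }
      ]
    },
    {
      "name": "RHCE_ex9",
      "group": "exon9",
      "source_class": "RHCE",
      "genomic_start": 25697014,
      "strand": "-",
      "primer_spans": {
        "forward": [1, 22],
        "reverse": [120, 148]
      },
      "diagnostic_sites": [
        {
          "amplicon_offset": 23,
          "genomic_pos": 25696992,
          "expected_base_by_source": {
            "RHD_wt": "A",
            "RHD_var": "A",
            "RHCE": "T"
          }
        },
        {
          "amplicon_offset": 57,
          "genomic_pos": 25696958,
          "expected_base_by_source": {
            "RHD_wt": "G",
            "RHD_var": "A",
            "RHCE": "C"
          }
        },
        {
          "amplicon_offset": 119,
          "genomic_pos": 25696896,
          "expected_base_by_source": {
            "RHD_wt": "A",
            "RHD_var": "A",
            "RHCE": "G"
          }
        }
      ]
    }
  ]
}
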