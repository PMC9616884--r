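name	priority	description	fair_tags	metadata_class	meaning_id
MetadataID	1	Unique and persistent identifier of the metadata	F1	unspecified	metadata_id
MetadataDate	1	Date of the metadata creation		intrinsic	metadata_date
AffiliateDatasetID	1	Globally unique identifier of the data, which the metadata is associated with	F3	unspecified	affiliate_dataset_id
MetadataVersion	1	Version of the Metadata		unspecified	metadata_version
ReferenceData	1	References to other data via name or description	I3	unspecified	reference_data
ReferenceMetadata	1	References to other metadata via name or description	I3	unspecified	reference_metadata
DataLifecycleState	2	State of the data during its lifecycle (creation, processing, analysis, preservation, access, reuse)		provenance	data_lifecycle_state
UsageLicense/Copyright	1	clear and accessible data usage license	R1.1	unspecified	usage_license_copyright
UsageContext	3	Context in which the data should be used		unspecified	usage_context
SourceSystemName	1	Explicit name of the Source System		unspecified	source_name
SourceSystemVersion	1	Version of the Source System when recording the (meta)data		unspecified	source_system_version
SourceInformation	3	Additional information about the source of the data		unspecified	source_information
SourceOriginalContributor	2	Contributor of the Source data		unspecified	source_contributor
VestingPeriod	3	Availability of data to other researcher outside the study during the time of the study		unspecified	vesting_period
ConsentType	2	Type of patient consent (i.e., broad consent, study specific consent)		unspecified	consent_type
ConsentValidation	1	Validity period of the consent		unspecified	consent_validation
ConsentVerification	1	Physical signature of the patient and start of the validity period		unspecified	consent_verification
ConsentModule	2	Exact parts of the consent, to which the patient consented to		unspecified	consent_module
DataItemLanguage	3	Language of the data items		unspecified	data_item_language
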